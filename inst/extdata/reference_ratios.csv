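source,pattern,aa,ratio
whole_milk,MMD,His,0.77
whole_milk,MMD,Ile,1.2
whole_milk,MMD,Leu,1.4
whole_milk,MMD,Lys,1.34
whole_milk,MMD,SAA,0.69
whole_milk,MMD,AAA,1.4
whole_milk,MMD,Thr,0.68
whole_milk,MMD,Trp,0.78
whole_milk,MMD,Val,1.06
whole_milk,FAO,His,1.84
whole_milk,FAO,Ile,1.32
whole_milk,FAO,Leu,1.5
whole_milk,FAO,Lys,1.72
whole_milk,FAO,SAA,1.28
whole_milk,FAO,AAA,2.43
whole_milk,FAO,Thr,1.7
whole_milk,FAO,Trp,1.69
whole_milk,FAO,Val,1.28
egg,MMD,His,0.5
egg,MMD,Ile,1.25
egg,MMD,Leu,1.14
egg,MMD,Lys,1.06
egg,MMD,SAA,0.88
egg,MMD,AAA,1.17
egg,MMD,Thr,0.66
egg,MMD,Trp,0.74
egg,MMD,Val,0.99
egg,FAO,His,1.19
egg,FAO,Ile,1.38
egg,FAO,Leu,1.21
egg,FAO,Lys,1.37
egg,FAO,SAA,1.64
egg,FAO,AAA,2.03
egg,FAO,Thr,1.66
egg,FAO,Trp,1.61
egg,FAO,Val,1.19
beef,MMD,His,1.02
beef,MMD,Ile,1.56
beef,MMD,Leu,1.33
beef,MMD,Lys,1.52
beef,MMD,SAA,1.04
beef,MMD,AAA,1.16
beef,MMD,Thr,0.74
beef,MMD,Trp,0.92
beef,MMD,Val,1.25
beef,FAO,His,2.44
beef,FAO,Ile,1.72
beef,FAO,Leu,1.42
beef,FAO,Lys,1.96
beef,FAO,SAA,1.94
beef,FAO,AAA,2.01
beef,FAO,Thr,1.87
beef,FAO,Trp,1.98
beef,FAO,Val,1.51
soy_protein_isolate,MMD,His,0.63
soy_protein_isolate,MMD,Ile,1.07
soy_protein_isolate,MMD,Leu,1.1
soy_protein_isolate,MMD,Lys,0.97
soy_protein_isolate,MMD,SAA,0.5
soy_protein_isolate,MMD,AAA,1.22
soy_protein_isolate,MMD,Thr,0.56
soy_protein_isolate,MMD,Trp,0.88
soy_protein_isolate,MMD,Val,0.79
soy_protein_isolate,FAO,His,1.6
soy_protein_isolate,FAO,Ile,1.27
soy_protein_isolate,FAO,Leu,1.25
soy_protein_isolate,FAO,Lys,1.24
soy_protein_isolate,FAO,SAA,1
soy_protein_isolate,FAO,AAA,2.24
soy_protein_isolate,FAO,Thr,1.52
soy_protein_isolate,FAO,Trp,2
soy_protein_isolate,FAO,Val,1.03
rice,MMD,His,0.54
rice,MMD,Ile,1.03
rice,MMD,Leu,1.13
rice,MMD,Lys,0.48
rice,MMD,SAA,0.88
rice,MMD,AAA,1.39
rice,MMD,Thr,0.55
rice,MMD,Trp,0.94
rice,MMD,Val,0.98
rice,FAO,His,1.3
rice,FAO,Ile,1.13
rice,FAO,Leu,1.21
rice,FAO,Lys,0.62
rice,FAO,SAA,1.64
rice,FAO,AAA,2.42
rice,FAO,Thr,1.39
rice,FAO,Trp,2.04
rice,FAO,Val,1.18
mung_bean,MMD,His,0.68
mung_bean,MMD,Ile,1.01
mung_bean,MMD,Leu,1
mung_bean,MMD,Lys,0.9
mung_bean,MMD,SAA,0.28
mung_bean,MMD,AAA,1.12
mung_bean,MMD,Thr,0.4
mung_bean,MMD,Trp,0.55
mung_bean,MMD,Val,0.83
mung_bean,FAO,His,1.62
mung_bean,FAO,Ile,1.11
mung_bean,FAO,Leu,1.07
mung_bean,FAO,Lys,1.17
mung_bean,FAO,SAA,0.52
mung_bean,FAO,AAA,1.95
mung_bean,FAO,Thr,1
mung_bean,FAO,Trp,1.2
mung_bean,FAO,Val,1.01
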