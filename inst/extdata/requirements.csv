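aa,mmd_demand,fao_requirement,body_protein
His,23,10,27
Ile,21,20,35
Leu,40,39,75
Lys,37,30,73
SAA,26,15,35
AAA,42,25,73
Thr,37,15,42
Trp,8,4,12
Val,30,26,49
total_protein,634,660,1000
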