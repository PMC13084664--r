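study,aa,unit,mean,sd,n_subjects,body_weight
ref_a,His,mg_per_day,247.5,50.25,18,75
ref_a,Ile,mg_per_day,19.125,1.2,10,75
ref_b,Ile,mg_per_day,22.05,1.4933333,30,70
ref_a,Leu,mg_per_day,25.5,3,10,75
ref_b,Leu,mg_per_day,29.4,3.7333333,30,70
ref_a,Lys,mg_per_day,63.75,12,10,75
ref_b,Lys,mg_per_day,73.5,14.933333,30,70
ref_a,Met,mg_per_day,44.625,12,10,75
ref_b,Met,mg_per_day,51.45,14.933333,30,70
ref_a,Cys,mg_per_day,31.875,13.416408,10,75
ref_b,Cys,mg_per_day,36.75,16.695974,30,70
ref_a,Phe,mg_per_day,38.25,9,10,75
ref_b,Phe,mg_per_day,44.1,11.2,30,70
ref_a,Tyr,mg_per_day,44.625,7.9372539,10,75
ref_b,Tyr,mg_per_day,51.45,9.8774716,30,70
ref_a,Thr,mg_per_day,57.375,6,10,75
ref_b,Thr,mg_per_day,66.15,7.4666667,30,70
ref_a,Trp,mg_per_day,38.25,6,10,75
ref_b,Trp,mg_per_day,44.1,7.4666667,30,70
ref_a,Val,mg_per_day,19.125,6,10,75
ref_b,Val,mg_per_day,22.05,7.4666667,30,70
ref_a,Ala,mg_per_day,70.125,24,10,75
ref_b,Ala,mg_per_day,80.85,29.866667,30,70
ref_a,Arg,mg_per_day,25.5,6,10,75
ref_b,Arg,mg_per_day,29.4,7.4666667,30,70
ref_a,Asp,mg_per_day,127.5,12,10,75
ref_b,Asp,mg_per_day,147,14.933333,30,70
ref_a,Asn,mg_per_day,89.25,13.416408,10,75
ref_b,Asn,mg_per_day,102.9,16.695974,30,70
ref_a,Glu,mg_per_day,255,60,10,75
ref_b,Glu,mg_per_day,294,74.666667,30,70
ref_a,Gly,mg_per_day,765,162,10,75
ref_b,Gly,mg_per_day,882,201.6,30,70
ref_a,Pro,mg_per_day,51,18,10,75
ref_b,Pro,mg_per_day,58.8,22.4,30,70
ref_a,Ser,mg_per_day,102,30,10,75
ref_b,Ser,mg_per_day,117.6,37.333333,30,70
ref_range,Gln,mmol_per_mol_creatinine,116.31885,33.520215,40,75
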