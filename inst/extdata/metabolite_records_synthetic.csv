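metabolite,parent_aa,excretion,excretion_sd,unit,stoichiometry
3-methylhistidine,His,0.00029004189,9.6680632e-05,mol_per_day,1
hydroxylysine,Lys,0.0001026062,2.0521239e-05,mol_per_day,1
taurine,Cys,0.00061901618,0.00055711456,mol_per_day,1
cystathionine,Met,0.00010052946,0.00015079418,mol_per_day,1
homocysteine,Met,5.0264728e-05,0.00015895103,mol_per_day,1
homovanillic_acid,Tyr,2.4835808e-05,8.2786026e-06,mol_per_day,1
vanillylmandelic_acid,Tyr,1.6557205e-05,9.2557591e-06,mol_per_day,1
5-hydroxyindoleacetic_acid,Trp,4.0395632e-05,1.1016991e-05,mol_per_day,1
kynurenic_acid,Trp,3.6723302e-05,1.1016991e-05,mol_per_day,1
xanthurenic_acid,Trp,3.3050972e-05,9.7160725e-06,mol_per_day,1
beta-aminoisobutyrate,Asp,11.269722,3.756574,mmol_per_mol_creatinine,1
creatinine,Gly,0.015,0.0019981351,mol_per_day,1
uric_acid,Gly,0.0021839616,0.0011347226,mol_per_day,1
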