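# Model constants for the 75-kg young adult male reference subject
io_rate: 0.29
pto_pa_fraction: 0.11
pto_pp_fraction: 0.024
n_to_protein: 6.25
body_weight: 75
creatinine_excretion: 0.2
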