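aa,mg_per_g
His,29.8125
Ile,25.3125
Leu,47.8125
Lys,58.9375
SAA,85.3125
AAA,33.9375
Thr,51.375
Trp,8.25
Val,42.4375
Ala,38.4375
Arg,198.375
Asx,43.25
Glx,82.375
Gly,98.125
Pro,51.25
Ser,107.5
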