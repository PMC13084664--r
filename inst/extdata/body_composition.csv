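aa,mg_per_g,provenance
His,27,reference
Ile,35,reference
Leu,75,reference
Lys,73,reference
SAA,35,reference
AAA,73,reference
Thr,42,reference
Trp,12,reference
Val,49,reference
Ala,65,synthetic
Arg,74,synthetic
Asx,92,synthetic
Glx,138,synthetic
Gly,110,synthetic
Pro,60,synthetic
Ser,40,synthetic
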