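component,mean,sd
io,183.9,12.7
pto_pp,62.2,51.8
pto_pa,155.1,28.2
egl,145.6,19.6
ufaap,35.9,3.7
hsnm,31.3,5.6
ol,20.1,2.7
mmd,634.1,62.6
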