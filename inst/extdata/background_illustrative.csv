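metal,background_mg_L
Cd,0.1
Cr,0.3
Cu,0.5
Mn,0.1
Ni,0.1
Pb,0.5
Zn,1.0
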