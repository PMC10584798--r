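# NEMA IEC sphere phantom, cold background
type: nema
sphere_conc: 1.6
background_conc: 0.0
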