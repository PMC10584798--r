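# Quantification-accuracy phantom: uniform cylinder
type: cylinder
diameter: 200.0
height: 180.0
activity: 700.0
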