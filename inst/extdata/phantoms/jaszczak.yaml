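# Calibration phantom: uniform cylinder of the Jaszczak body dimensions
type: cylinder
diameter: 209.0
height: 186.0
activity: 541.0
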