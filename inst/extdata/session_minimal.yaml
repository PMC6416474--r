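# Minimal shorthand form: everything else takes package defaults.
fluence_rate: 50
time: 600
BPD: 0.53
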