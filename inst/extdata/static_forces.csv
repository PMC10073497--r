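label,force_N
S01,210.5
S02,299.6
S03,262.0
S04,236.6
S05,263.9
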