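label,force_N,precondition_force_N,peak_stress_MPa,precondition_stress_MPa
E01,127.3,15,1824.5,220.1
E02,63.6,15,940,220.1
E03,44.5,15,658.6,220.1
E04,35.6,15,526.2,220.1
E05,40.1,15,593.2,220.1
E06,42.3,15,525.9,220.1
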