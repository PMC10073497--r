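label,force_N,life_cycles,censored,note
E01,127.3,1230,0,failure at bridge mobile side
E02,63.6,23262,0,failure at bridge mobile side
E03,44.5,78567,0,failure at bridge mobile side
E04,35.6,100000,1,no failure
E05,40.1,100000,1,no failure
E06,42.3,100000,1,no failure
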