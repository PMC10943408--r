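reduction_pct,societal_savings_busd
25,4.34
50,8.17
75,12.75
100,15.60
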