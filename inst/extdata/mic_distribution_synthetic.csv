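mic_mg_per_L,frequency
0.06,0.30
0.125,0.20
0.25,0.13
0.5,0.09
1,0.07
2,0.06
4,0.06
8,0.05
16,0.04
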