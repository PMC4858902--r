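# parasite 6 10
0100100011
0000011110
0000001001
0100100011
0000011110
0000001001
0100100011
0000011110
0000001001
0100100011
1111011110
0000001001
0100100011
1111011110
0000001001
0100100011
1111011110
0000001001
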