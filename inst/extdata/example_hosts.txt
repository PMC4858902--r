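# host 4 10
0110100001
1101101101
1001010001
1111110001
0001110100
1110011001
1000110101
1111100100
0011111100
0101110010
0001110001
1100010110
1010100110
1101111100
1111110010
1000101001
0010100011
1101110101
1110001111
1111000100
1101010011
1001011110
0100010011
1011011010
0000101101
0110111100
0000110011
0001101101
0100101010
0000111001
0000000101
0100101000
1100110000
0100001000
0101010001
1111000100
0001000101
1100010111
0100001011
0100011011
1001000110
1000010011
1110100101
1101101001
0111011110
1101000001
1001001011
0001011000
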