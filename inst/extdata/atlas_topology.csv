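parent,child,multiplicity
B1,B2,1
B1,B14,1
B1,B28,1
B28,B26,1
B28,B27,1
B2,B3,9
B2,B4,2
B2,B5,1
B4,B6,1
B6,B7,1
B7,B8,1
B7,B9,1
B7,B10,16
B14,B19,1
B14,B15,1
B14,B20,9
B15,B22,15
B15,B23,1
B15,B12,1
B15,B16,1
B16,B21,1
B16,B17,1
B17,B18,1
B19,B24,7.6
B19,B25,1
B37,B29,1
B37,B30,1
B37,B31,1
B37,B32,1
B37,B38,1
B38,B33,1
B38,B34,1
B38,B35,1
B38,B36,1
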