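category	total	detected
1	110	49
2	55	29
3	195	73
4	41	10
5	160	8
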