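rs101	rs102	rs103	rs104	rs105	rs106	rs107	rs108
1.000000	0.500000	0.250000	0.125000	0.062500	0.031250	0.015625	0.007812
0.500000	1.000000	0.500000	0.250000	0.125000	0.062500	0.031250	0.015625
0.250000	0.500000	1.000000	0.500000	0.250000	0.125000	0.062500	0.031250
0.125000	0.250000	0.500000	1.000000	0.500000	0.250000	0.125000	0.062500
0.062500	0.125000	0.250000	0.500000	1.000000	0.500000	0.250000	0.125000
0.031250	0.062500	0.125000	0.250000	0.500000	1.000000	0.500000	0.250000
0.015625	0.031250	0.062500	0.125000	0.250000	0.500000	1.000000	0.500000
0.007812	0.015625	0.031250	0.062500	0.125000	0.250000	0.500000	1.000000
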