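ID	A1	A2	Z
rs101	A	G	-0.508394
rs102	C	T	0.139818
rs103	G	A	-1.196396
rs104	T	C	-1.636932
rs105	A	G	-1.047709
rs106	C	T	-1.397420
rs107	G	A	-2.101883
rs108	T	C	-1.320354
rs999	A	G	0.500000
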