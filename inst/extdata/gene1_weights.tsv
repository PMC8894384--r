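ID	tissueA	tissueB
rs101	1.809078	0.200093
rs102	0.096472	-1.041226
rs103	0.365964	1.627148
rs104	-0.652991	0.550392
rs105	0.151818	-1.457135
rs106	0.333700	-0.827871
rs107	1.633710	1.487948
rs108	2.289488	-0.837978
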