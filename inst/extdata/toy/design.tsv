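sample_id	ingredient	matrix	burial	replicate	cofire_group	run_order
S_deer	T_DEER	foodcrust	unburied	1	FIRE1	1
W1		wash	unburied	1		2
S_chest	T_CHST	foodcrust	unburied	1	FIRE1	3
W2		wash	unburied	1		4
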