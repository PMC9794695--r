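sample_id	role	replicate	generation
P1_1	P1	1	parent
P1_2	P1	2	parent
P2_1	P2	1	parent
P2_2	P2	2	parent
F1_1	F1	1	F1
F1_2	F1	2	F1
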