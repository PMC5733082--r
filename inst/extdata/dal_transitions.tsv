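from_type	to_type	only_negative	only_positive	both
IV	I	5	8	22
IV	II	66	95	133
IV	III	59	63	83
I	IV	9	7	21
I	II	53	53	111
I	III	21	28	24
II	IV	73	59	113
II	I	40	61	43
II	III	0	0	0
III	IV	85	55	63
III	I	16	20	33
III	II	0	0	1
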