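library	clone	yield_mg_per_l	pct_monomer
T	TF8	21	86
T	TE6	32	65
T	TD4	22	58
T	TD3	32	70
T	TC11	26	77
S	SG10	12.4	75
S	SF9	4.1	34
S	SB10	5.8	79
S	SD7	23.3	35
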