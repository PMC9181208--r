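antigen	library	round	elisa_positive	screened	unique	sequenced
hNinj1	T-kappa	3	91	94	2	5
hNinj1	T-kappa	4	93	94	NA	NA
hNinj1	T-lambda	3	52	94	4	6
hNinj1	T-lambda	4	94	94	2	6
hNinj1	S-kappa	3	66	94	1	4
hNinj1	S-kappa	4	NA	NA	NA	NA
hNinj1	S-lambda	3	4	94	3	7
hNinj1	S-lambda	4	8	94	2	3
CARS	T-kappa	3	91	94	3	8
CARS	T-kappa	4	91	94	2	10
CARS	T-lambda	3	91	94	7	8
CARS	T-lambda	4	92	94	8	8
CARS	S-kappa	3	46	94	10	12
CARS	S-kappa	4	89	94	5	9
CARS	S-lambda	3	91	94	5	10
CARS	S-lambda	4	94	94	3	8
AgX	T-kappa	3	48	94	4	8
AgX	T-kappa	4	24	94	6	9
AgX	T-lambda	3	19	94	10	13
AgX	T-lambda	4	10	94	7	7
AgX	S-kappa	3	16	94	11	13
AgX	S-kappa	4	2	94	2	2
AgX	S-lambda	3	5	94	3	3
AgX	S-lambda	4	4	94	1	1
BCMA	T-kappa	4	NA	NA	NA	NA
BCMA	T-lambda	4	90	94	5	11
BCMA	S-kappa	4	2	47	2	2
BCMA	S-lambda	4	1	47	1	1
CD22	T-kappa	4	NA	NA	NA	NA
CD22	T-lambda	4	92	94	3	8
CD22	S-kappa	4	12	94	2	6
CD22	S-lambda	4	27	94	2	8
HEWL	T-kappa	4	1	188	1	1
HEWL	T-lambda	4	4	188	3	4
HEWL	S-kappa	4	24	94	1	6
HEWL	S-lambda	4	45	94	5	25
SARS	T-lambda	4	80	94	4	5
SARS	S-kappa+lambda	4	16	94	3	14
AIMP1	T-lambda	4	86	94	5	5
AIMP1	S-kappa+lambda	4	66	94	5	8
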