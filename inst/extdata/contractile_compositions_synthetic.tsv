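protein_id	alanine	arginine	asparagine	aspartate	cysteine	glutamate	glutamine	glycine	histidine	isoleucine	leucine	lysine	methionine	phenylalanine	proline	serine	threonine	tryptophan	tyrosine	valine
actin	29	24	11	12	8	19	11	29	14	32	32	20	14	14	21	30	21	1	12	21
myhc_1_2x	182	103	63	109	26	124	72	146	38	94	181	116	42	94	98	129	99	24	61	134
myhc_2a	163	95	81	119	24	125	85	138	55	92	193	112	38	61	101	136	111	26	67	119
myhc_2b	162	114	72	119	30	114	81	129	39	127	194	107	50	67	91	128	95	32	55	133
mylk	8	10	5	9	4	9	5	17	5	14	11	9	5	7	7	13	12	3	9	10
mylp	11	15	5	9	4	11	8	12	2	9	12	12	7	6	9	10	8	3	4	9
tpm_1	22	17	9	24	5	25	11	26	4	18	22	13	6	10	15	24	15	3	7	8
tpm_2	29	14	14	10	4	23	15	13	5	16	19	13	8	10	19	21	18	5	8	20
tnnc_1	27	11	7	7	1	13	6	11	4	9	10	12	2	3	6	9	8	3	3	10
tnni_1	14	9	9	12	2	12	4	12	6	9	23	10	7	7	8	15	9	2	5	12
tnnt_1	24	14	11	12	3	19	8	16	3	17	25	10	6	17	20	17	11	3	8	14
tnnc_2	14	9	7	6	3	7	7	13	5	10	19	3	3	5	11	12	11	4	2	9
tnni_2	11	9	7	11	2	8	6	9	7	8	21	11	6	10	9	12	13	2	6	14
tnnt_2	33	14	9	17	6	15	7	14	4	12	33	10	6	9	19	15	25	1	17	22
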