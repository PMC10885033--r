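gene_id	myob_fpkm	myob_ratio	cbl_tpm	cbl_ratio	n_hypo	n_hyper
ZNF556	12	1076	2	27	1	0
CDH15	164	560	141	1441	1	2
TRIM72	43	127	12	53	1	1
ANK1	29	15	85	25	2	1
MCF2L	21	5	110	9	2	3
DOK7	45	220	21	27	0	1
CNPY1	2	39	26	158	0	2
KCNJ12	5	6	81	40	0	3
ST8SIA5	4	6	51	14	0	1
ZIC1	5	39	311	57	0	14
VAX2	4	6	19	15	0	7
EN2	3	56	68	201	0	4
LBX1	1	230	3	78	0	4
PAX3	1	23	4	28	0	11
CHRD	4	7	243	22	1	0
FNDC5	64	88	109	8	0	0
PLCB4	54	22	57	18	0	0
MPP4	9	9	3	16	0	0
PTPRR	2	6	22	9	0	0
IL11	6	6	6	14	0	0
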