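name	sequence	rawFree	rawTreated	normFree	normTreated	log2fc	origin	familySize
PC-28-3p	CATTTGGGCACCTATTTTGACTC	24	2	25.36	1.89	-3.74	novel	1
PN-miR164	TGGAGAAGCAGGGCACGTGCA	95	12	100.39	11.36	-3.14	known	1
PN-miR2111	CTAGTCCTTGGGATGCAGATTACG	57	10	60.23	9.46	-2.67	known	1
PC-1-5p	TGGCCTGTGATGCATCAATTTGTC	49	10	51.78	9.46	-2.45	novel	1
PC-4-5p	GTCGTTGTAGTATAGTGGTAAGT	26	8	27.47	7.57	-1.86	novel	1
PN-miR5044	GTAGTGGATGCCTAGAGGTCC	25	8	26.42	7.57	-1.80	known	1
PN-miR156b,c,d	TGACAGAAGAGAGTGAGCAC	369	137	389.92	129.65	-1.59	known	3
gso-mir2109-p3	GGAGGCGTAGATACTCACACC	2655	1201	2805.55	1136.55	-1.30	known	1
PC-46-5p	CTATATGATGAAGATA	52	26	54.95	24.60	-1.16	novel	1
PN-miR1507c	CCTCATTCCAAACATCATCTAA	377	194	398.38	183.59	-1.12	known	1
gso-miR2218	TTGCCGATTCCACCCATTCCTA	7282	19061	7694.91	18038.15	1.23	known	1
PN-miR169c	AAGCCAAGGATGACTTGCCGA	17	47	17.96	44.48	1.31	known	1
PN-miR390b	AAGCTCAGGAGGGATAGCACC	13	36	13.74	34.07	1.31	known	1
PN-miR862a,b	GCTGGATGTCTTTGAAGGAAT	113	355	119.41	335.95	1.49	known	2
PC-39-5p	TAGATTTTAAAGTTGCGGATCA	10	32	10.57	30.28	1.52	novel	1
gso-mir1509a-p3	ACCGTGTTTCCTTGGTTAACG	9	34	9.51	32.18	1.76	known	1
PC-25-3p	CTACATAAGGCACGAGATCATC	7	29	7.40	27.44	1.89	novel	1
gso-mir1510a-p5	AGGGATAGGTAAAACAATGAC	6	25	6.34	23.66	1.90	known	1
PN-miR4387e-p5	TCACGCCTAATCACTGACGCA	11	49	11.62	46.37	2.00	known	1
PN-miR1514a	TTCATTTTTAAAATAGGCATTGGG	11	51	11.62	48.26	2.05	known	1
PN-mir4415-p3	TTGATTCTCATCACAACATGG	41	243	43.32	229.96	2.41	known	1
PC-33-3p	GGAGAACAAAGAAGCAGCTAAATTC	4	29	4.23	27.44	2.70	novel	1
PN-miR4369	GGATCAAGCTGATCCGGAAGTGGA	3	23	3.17	21.77	2.78	known	1
PN-miR396a-1	TTCCACAGCTTTCTTGAACTG	81	676	85.59	639.72	2.90	known	1
PN-miR403a,b	TTAGATTCACGCACAAACTTG	5	44	5.28	41.64	2.98	known	2
PN-miR1509b	TTAATCAAGGAAATCACGGTTG	190	2232	200.77	2112.23	3.40	known	1
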