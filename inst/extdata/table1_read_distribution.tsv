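class	treatedCount	treatedPct	freeCount	freePct
raw	8616284	100.00	8712410	100.00
adapter_not_found	974498	11.31	1411300	16.20
too_short_after_trim	345537	4.01	260266	2.99
junk	8594	0.10	4930	0.06
mapped	7287655	84.58	7035914	80.76
mRNA	6310043	86.59	6114595	86.91
rfam	192054	2.64	164494	2.34
repeats	2976	0.04	2140	0.03
miRNA	184734	2.53	124343	1.77
no_hit	597848	8.20	630342	8.96
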