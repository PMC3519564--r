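mirna	target	score	site	categoryTreated	percentTreated	tpbTreated	categoryFree	percentFree	tpbFree	family
PC-46-5p	Glyma03g33240	1	2649	2	0.50	96.53	NA	NA	NA	Cation transporting ATPase
PC-46-5p	Glyma05g23260	1.5	3244	NA	NA	NA	2	0.68	121.15	Protein tyrosine kinase
PC-46-5p	Glyma13g03270	3.5	1559	2	1.33	38.61	2	2.01	60.57	TPR repeat-containing protein
PC-46-5p	Glyma14g23650	3.5	961	2	1.06	38.61	2	1.47	60.57	TPR repeat-containing protein
PC-46-5p	Glyma19g35960	1	2649	2	0.51	96.53	NA	NA	NA	Cation transporting ATPase
gso-mir167a-p3	Glyma13g04540	3.5	1822	3	0.07	58.99	NA	NA	NA	Lipase (class3)
PN-mir156f-p3	Glyma03g27590	3	333	2	0.17	96.53	2	0.17	121.15	Transcription elongation factor SPT6
PN-mir156f-p3	Glyma19g30560	3	206	2	0.14	96.53	2	0.25	121.15	Transcription elongation factor SPT6
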