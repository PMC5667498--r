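locus	region	t_my	excluded	note
1p36.13	ltr_vs_ltr	14.1	FALSE	
1p36.13	ltr_vs_consensus	21.0	FALSE	
1p36.13	gag	22.5	FALSE	
1p36.13	env	31.9	FALSE	
1p22.2	env	45.0	FALSE	
1q22	ltr_vs_ltr	14.7	FALSE	
1q22	ltr_vs_consensus	44.1	FALSE	
1q22	gag	35.7	FALSE	
1q22	pol	28.9	FALSE	
1q22	env	32.7	FALSE	
6p22.1	ltr_vs_ltr	12.7	FALSE	
6p22.1	ltr_vs_consensus	36.5	FALSE	
6p22.1	gag	43.0	FALSE	
6p22.1	pol	18.9	FALSE	
6p22.1	env	32.8	FALSE	
6p21.33a	ltr_vs_ltr	22.9	FALSE	
6p21.33a	ltr_vs_consensus	18.0	FALSE	
6p21.33a	gag	25.2	FALSE	
6p21.33a	pol	21.3	FALSE	
6p21.33a	env	21.3	FALSE	
6p21.33b	ltr_vs_ltr	22.9	FALSE	
6p21.33b	ltr_vs_consensus	18.0	FALSE	
6p21.33b	gag	25.2	FALSE	
6p21.33b	pol	21.3	FALSE	
6p21.33b	env	21.3	FALSE	
6q22.31	ltr_vs_ltr	17.2	FALSE	
6q22.31	ltr_vs_consensus	38.8	FALSE	
6q22.31	gag	38.9	FALSE	
6q22.31	pol	44.8	FALSE	
6q22.31	env	35.1	FALSE	
19p13.2	gag	165.7	TRUE	highly divergent gag; excluded from the locus mean
19p13.2	pol	20.8	FALSE	
19q13.41	ltr_vs_consensus	46.0	FALSE	
19q13.41	gag	37.4	FALSE	
19q13.41	pol	27.2	FALSE	
19q13.41	env	45.9	FALSE	
Yq11.221	ltr_vs_ltr	20.8	FALSE	
Yq11.221	ltr_vs_consensus	45.2	FALSE	
Yq11.221	gag	41.5	FALSE	
Yq11.221	pol	30.4	FALSE	
Yq11.221	env	44.7	FALSE	
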