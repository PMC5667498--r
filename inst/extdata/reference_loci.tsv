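name	chrom	start	end	strand	context	duplicate_of
1p36.13	1	20253380	20259203	-	intergenic	
1p22.2	1	89551973	89554309	+	intergenic	
1q22	1	155661620	155669312	-	DAP3	
6p22.1	6	27155300	27164058	+	intergenic	
6p21.33a	6	31952469	31958829	-	C4A	
6p21.33b	6	31985207	31991567	-	C4B	6p21.33a
6q22.31	6	122825990	122833238	-	PKIB	
19p13.2	19	7860947	7865932	-	intergenic	
19q13.41	19	52964148	52969750	-	ZNF578	
Yq11.221	Y	15105784	15113006	-	L1M3f	
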