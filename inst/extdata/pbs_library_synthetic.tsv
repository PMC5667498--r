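trna	sequence	name
K	TGGCGCCCAACGTGGGGC	lysine_exemplar_synthetic
R	TGGCGCCCGAACAGGGAC	arginine_decoy_synthetic
W	TGGTACCCAACATGGGAG	tryptophan_decoy_synthetic
H	TGGTAGCAGAGGCTCGGA	histidine_decoy_synthetic
F	TGGTGCCGAAACCCGGGA	phenylalanine_decoy_synthetic
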