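TLS_9gene	Cabrita et al. melanoma TLS signature (differential expression derived)	CD79B	CD1D	CCR6	LAT	SKAP1	CETP	EIF1AY	RBP5	PTGDS
TLS_hallmark_7gene	Cabrita et al. TLS hallmark gene compendium signature	CCL19	CCL21	CXCL13	CCR7	CXCR5	SELL	LAMP3
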