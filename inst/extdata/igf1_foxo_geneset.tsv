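# Gene-set membership: the IGF1/FoxO signalling pathway candidate set.
set	gene_id
IGF1_FoxO	IGF1
IGF1_FoxO	IGFBP1
IGF1_FoxO	IGFBP2
IGF1_FoxO	IGFBP3
IGF1_FoxO	IGFBP4
IGF1_FoxO	IGFBP5
IGF1_FoxO	IGFBP6
IGF1_FoxO	INSR
IGF1_FoxO	IRS1
IGF1_FoxO	IRS4
IGF1_FoxO	PIK3R1
IGF1_FoxO	PIK3R2
IGF1_FoxO	PIK3R3
IGF1_FoxO	PDK1
IGF1_FoxO	PDK2
IGF1_FoxO	PDK3
IGF1_FoxO	PDK4
IGF1_FoxO	AKT1
IGF1_FoxO	AKT2
IGF1_FoxO	AKT3
IGF1_FoxO	FOXO1
IGF1_FoxO	FOXO3
IGF1_FoxO	FOXO4
IGF1_FoxO	FOXO6
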