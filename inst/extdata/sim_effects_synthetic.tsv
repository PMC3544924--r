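# Synthetic per-QTN effect table for the mixed additive/dominance/epistasis
# simulation scenario: 13 causal QTNs on the default 57-SNP panel, additive
# effects drawn once from N(0,1), dominance effects from N(0,0.5), frozen.
# Override with any TSV carrying the same columns.
snp_id	additive	dominance
snp0003	-1.2597	0.1177
snp0004	1.2667	-0.0214
snp0012	1.0404	0.0862
snp0015	-0.8369	0.589
snp0016	-0.4945	-0.8484
snp0017	-1.1024	0.2693
snp0021	0.9831	1.4937
snp0027	0.0532	-1.1204
snp0042	-0.6502	0.2976
snp0044	0.3047	-0.5575
snp0046	-1.7803	-0.5112
snp0050	-1.0831	0.7201
snp0054	-0.415	-0.3586
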