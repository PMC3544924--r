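# Synthetic epistatic pair list: three non-overlapping QTN pairs whose
# effect is expressed only when an individual is heterozygous at both
# members; effect magnitudes fixed at 1.
pair_id	snp1	snp2	effect
pair1	snp0012	snp0054	1
pair2	snp0050	snp0004	-1
pair3	snp0003	snp0044	1
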