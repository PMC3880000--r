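# MCA whole-chromosome paints hybridized onto the LCO karyotype.
# One row per painted block, ordered pter->qter within each target chromosome.
# "alternatives" as in the ACU fixture: arm-level "or" ambiguity, source chromosome certain.
# LCO 9 carries an intact but inverted MCA 9 homolog.
target_species	target_chrom	order_index	target_region	source_species	source_region	alternatives	flags
LCO	1	1	1p	MCA	10
LCO	1	2	1qp	MCA	11
LCO	1	3	1qt	MCA	14
LCO	2	1	2p	MCA	5q
LCO	2	2	2qp	MCA	6p
LCO	2	3	2qt	MCA	6q
LCO	3	1	3pt	MCA	2p	2q
LCO	3	2	3pp	MCA	18
LCO	3	3	3q	MCA	1q
LCO	4	1	4p	MCA	1p
LCO	4	2	4q	MCA	12
LCO	5	1	5p	MCA	3p
LCO	5	2	5qp	MCA	17
LCO	5	3	5qt	MCA	7q
LCO	6	1	6p	MCA	13qp
LCO	6	2	6q	MCA	4p	4q
LCO	7	1	7p	MCA	15
LCO	7	2	7q	MCA	2q	2p
LCO	8	1	8p	MCA	7p
LCO	8	2	8qi	MCA	13qd
LCO	8	3	8qd	MCA	3q
LCO	9	1	9	MCA	9		inverted
LCO	10	1	10	MCA	8
LCO	11	1	11p/qp	MCA	16
LCO	11	2	11qt	MCA	19
LCO	12	1	12	MCA	4q	4p
LCO	13	1	13	MCA	5p
LCO	X	1	X	MCA	X
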