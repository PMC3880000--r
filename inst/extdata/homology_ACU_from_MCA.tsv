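# MCA whole-chromosome paints hybridized onto the ACU karyotype.
# One row per painted block (or explicit unpainted gap), ordered pter->qter within each
# target chromosome. "alternatives" records unresolved "or" placements: in every case the
# two alternatives are the two arms of one MCA chromosome, so the source chromosome is
# certain and only the arm assignment is ambiguous.
# ACU 8, 10, 11 carry intact but inverted/centromere-shifted MCA homologs.
target_species	target_chrom	order_index	target_region	source_species	source_region	alternatives	flags
ACU	1	1	1pt	MCA	12
ACU	1	2	1pp	MCA	5q
ACU	1	3	1qp	MCA	16q
ACU	1	4	1qi	MCA	9p
ACU	1	5	1qi	MCA	17
ACU	1	6	1qt	MCA	14
ACU	2	1	2p	MCA	6p	6q
ACU	2	2	2qp	MCA	13qp
ACU	2	3	2qt	MCA	3q	3p
ACU	3	1	3p	MCA	6q	6p
ACU	3	2	3q	MCA	1q
ACU	4	1	4p				gap
ACU	4	2	4qp	MCA	1p
ACU	4	3	4qd	MCA	4p	4q
ACU	5	1	5p	MCA	5p
ACU	5	2	5qp	MCA	18qp
ACU	5	3	5qi	MCA	13qd
ACU	5	4	5qd	MCA	3p	3q
ACU	6	1	6pt	MCA	16p
ACU	6	2	6pp	MCA	19
ACU	6	3	6qp	MCA	18qd
ACU	6	4	6qd	MCA	15
ACU	7	1	7	MCA	2p	2q
ACU	8	1	8	MCA	10		inverted
ACU	9	1	9	MCA	2q	2p
ACU	10	1	10	MCA	7		inverted
ACU	11	1	11	MCA	11		inverted
ACU	12	1	12	MCA	8
ACU	13	1	13	MCA	4q	4p
ACU	14	1	14	MCA	9q
ACU	X	1	X	MCA	X
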