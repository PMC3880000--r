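# MCA whole-chromosome paints hybridized onto the GSO karyotype.
# One row per painted block (or explicit unpainted gap), ordered pter->qter within each
# target chromosome. The two MCA 5-derived signals on GSO 1p are separated by
# unpainted heterochromatin and are encoded as distinct blocks.
# GSO 15p is the unpainted NOR-bearing short arm (MCA 19 is acrocentric).
target_species	target_chrom	order_index	target_region	source_species	source_region	alternatives	flags
GSO	1	1	1pt	MCA	5qd
GSO	1	2	1pi				gap
GSO	1	3	1pp	MCA	5qp
GSO	1	4	1q	MCA	10
GSO	2	1	2p	MCA	12
GSO	2	2	2q	MCA	2q
GSO	3	1	3p/qp	MCA	13
GSO	3	2	3qd	MCA	3q
GSO	4	1	4p	MCA	14
GSO	4	2	4q	MCA	1q
GSO	5	1	5p	MCA	3p
GSO	5	2	5q	MCA	11
GSO	6	1	6p	MCA	2p
GSO	6	2	6q	MCA	1p
GSO	7	1	7p	MCA	4p
GSO	7	2	7q	MCA	4q
GSO	8	1	8p/qp	MCA	9
GSO	8	2	8qt	MCA	17
GSO	9	1	9p	MCA	6p
GSO	9	2	9q	MCA	6q
GSO	10	1	10	MCA	7
GSO	11	1	11	MCA	8
GSO	12	1	12p/qp	MCA	18
GSO	12	2	12qt	MCA	5p
GSO	13	1	13	MCA	16
GSO	14	1	14	MCA	15
GSO	15	1	15p				gap
GSO	15	2	15q	MCA	19		NOR-adjacent
GSO	X	1	X	MCA	X
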