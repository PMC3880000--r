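# Human (HSA) chromosome segment content of GSO chromosome regions (ECU-space homologies
# re-expressed on the GSO karyotype, including the recently refined segments
# GSO 3qp: HSA 13; GSO 8q: HSA 8b-4c; GSO 13: HSA 19a; GSO 9q: HSA 8).
# source_region holds opaque HSA segment-content strings, not cytogenetic region labels.
target_species	target_chrom	order_index	target_region	source_species	source_region	alternatives	flags
GSO	1	1	1p	HSA	4a:10b
GSO	1	2	1q	HSA	14a-15a-14b-15b
GSO	2	1	2p	HSA	2a
GSO	2	2	2q	HSA	6a
GSO	3	1	3p	HSA	12a-22a
GSO	3	2	3qp	HSA	13b
GSO	3	3	3qd	HSA	3a-21
GSO	4	1	4p	HSA	9
GSO	4	2	4q	HSA	5a:7b:16b
GSO	5	1	5p	HSA	10a
GSO	5	2	5q	HSA	1a-6b
GSO	6	1	6p	HSA	2b
GSO	6	2	6q	HSA	11a
GSO	7	1	7p	HSA	3b
GSO	7	2	7q	HSA	8a
GSO	8	1	8p	HSA	13a
GSO	8	2	8qp	HSA	8b-4c
GSO	8	3	8qt	HSA	11b-22b-12b
GSO	9	1	9p	HSA	17
GSO	9	2	9q	HSA	4b:8:19b
GSO	10	1	10	HSA	18:20
GSO	11	1	11	HSA	7a
GSO	12	1	12p/qp	HSA	5b
GSO	12	2	12qt	HSA	1c
GSO	13	1	13	HSA	16a:19a
GSO	14	1	14	HSA	1b
GSO	15	1	15q	HSA	15c
GSO	X	1	X	HSA	X
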