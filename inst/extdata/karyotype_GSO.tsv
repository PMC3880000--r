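# Glossophaga soricina (GSO) karyotype, haploid representation, one row per pair.
# 2n = 32; FN = 60 (15 bi-armed autosome pairs; male X + Y). GSO 15 is the NOR-bearing pair.
species	chrom	morphology	is_sex
GSO	1	metacentric	FALSE
GSO	2	metacentric	FALSE
GSO	3	submetacentric	FALSE
GSO	4	metacentric	FALSE
GSO	5	submetacentric	FALSE
GSO	6	metacentric	FALSE
GSO	7	submetacentric	FALSE
GSO	8	submetacentric	FALSE
GSO	9	submetacentric	FALSE
GSO	10	metacentric	FALSE
GSO	11	submetacentric	FALSE
GSO	12	submetacentric	FALSE
GSO	13	metacentric	FALSE
GSO	14	submetacentric	FALSE
GSO	15	subtelocentric	FALSE
GSO	X	submetacentric	TRUE
GSO	Y	acrocentric	TRUE
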