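# Macrotus californicus (MCA) karyotype, haploid representation, one row per pair.
# 2n = 40; FN = 60 (19 autosome pairs: 11 bi-armed + 8 acrocentric; male X + Y).
species	chrom	morphology	is_sex
MCA	1	metacentric	FALSE
MCA	2	metacentric	FALSE
MCA	3	submetacentric	FALSE
MCA	4	submetacentric	FALSE
MCA	5	submetacentric	FALSE
MCA	6	submetacentric	FALSE
MCA	7	submetacentric	FALSE
MCA	8	subtelocentric	FALSE
MCA	9	submetacentric	FALSE
MCA	10	acrocentric	FALSE
MCA	11	acrocentric	FALSE
MCA	12	subtelocentric	FALSE
MCA	13	acrocentric	FALSE
MCA	14	acrocentric	FALSE
MCA	15	acrocentric	FALSE
MCA	16	subtelocentric	FALSE
MCA	17	acrocentric	FALSE
MCA	18	acrocentric	FALSE
MCA	19	acrocentric	FALSE
MCA	X	submetacentric	TRUE
MCA	Y	acrocentric	TRUE
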