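# Lonchophylla concava (LCO) karyotype, haploid representation, one row per pair.
# 2n = 28; FN = 50 (13 autosome pairs: 12 bi-armed + 1 acrocentric; male X + Y).
species	chrom	morphology	is_sex
LCO	1	submetacentric	FALSE
LCO	2	submetacentric	FALSE
LCO	3	submetacentric	FALSE
LCO	4	metacentric	FALSE
LCO	5	submetacentric	FALSE
LCO	6	submetacentric	FALSE
LCO	7	submetacentric	FALSE
LCO	8	submetacentric	FALSE
LCO	9	submetacentric	FALSE
LCO	10	metacentric	FALSE
LCO	11	submetacentric	FALSE
LCO	12	metacentric	FALSE
LCO	13	acrocentric	FALSE
LCO	X	submetacentric	TRUE
LCO	Y	acrocentric	TRUE
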