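# Anoura cultrata (ACU) karyotype, haploid representation, one row per pair.
# 2n = 30; FN = 56 (14 bi-armed autosome pairs; male X + Y).
# ACU 8 and 11 metacentric (homologs of acrocentric MCA 10 and 11); ACU 10 subtelocentric.
species	chrom	morphology	is_sex
ACU	1	submetacentric	FALSE
ACU	2	submetacentric	FALSE
ACU	3	metacentric	FALSE
ACU	4	submetacentric	FALSE
ACU	5	submetacentric	FALSE
ACU	6	submetacentric	FALSE
ACU	7	metacentric	FALSE
ACU	8	metacentric	FALSE
ACU	9	submetacentric	FALSE
ACU	10	subtelocentric	FALSE
ACU	11	metacentric	FALSE
ACU	12	submetacentric	FALSE
ACU	13	metacentric	FALSE
ACU	14	submetacentric	FALSE
ACU	X	submetacentric	TRUE
ACU	Y	acrocentric	TRUE
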