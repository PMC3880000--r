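# Chiropteran Evolutionarily Conserved Units (ECUs) expressed as human (HSA) chromosome
# segments, one row per MCA chromosome arm (25 rows = 25 ECUs). arm "w" = whole chromosome.
# In hsa_segments, ":" joins segments fused within one unit, "-" marks conserved
# adjacencies, "+" separates sub-blocks of one unit.
chrom	arm	ecu_id	hsa_segments
1	p	11a	11a
1	q	5a:7b:16b	5a:7b:16b
2	p	2b	2b
2	q	6a	6a
3	p	10a	10a
3	q	3a-21	3a-21
4	p	3b	3b
4	q	8a	8a
5	p	1c	1c
5	q	4a:10b	4a:10b
6	p	17	17
6	q	4b:8:19b	4b:8:19b
7	w	18:20	18:20
8	w	7a	7a
9	w	13a:8b-4c	13a:8b-4c
10	w	14a-15a-14b-15b	14a-15a-14b-15b
11	w	1a-6b	1a-6b
12	w	2a	2a
13	w	12a-22a+13b	12a-22a+13b
14	w	9	9
15	w	1b	1b
16	w	16a:19a	16a:19a
17	w	11b-22b-12b	11b-22b-12b
18	w	5b	5b
19	w	15c	15c
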