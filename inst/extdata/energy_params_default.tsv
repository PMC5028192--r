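kind	key	kcal_per_mol
STACK	AA/UU	-0.93
STACK	AU/UA	-1.1
STACK	AC/UG	-2.24
STACK	AG/UC	-2.08
STACK	AG/UU	-1.3
STACK	AU/UG	-1.3
STACK	UA/AU	-1.33
STACK	UU/AA	-0.93
STACK	UC/AG	-2.35
STACK	UG/AC	-2.11
STACK	UG/AU	-1.3
STACK	UU/AG	-1.3
STACK	CA/GU	-2.11
STACK	CU/GA	-2.08
STACK	CC/GG	-3.26
STACK	CG/GC	-2.36
STACK	CG/GU	-1.3
STACK	CU/GG	-1.3
STACK	GA/CU	-2.35
STACK	GU/CA	-2.24
STACK	GC/CG	-3.42
STACK	GG/CC	-3.26
STACK	GG/CU	-1.3
STACK	GU/CG	-1.3
STACK	GA/UU	-1.3
STACK	GU/UA	-1.3
STACK	GC/UG	-1.3
STACK	GG/UC	-1.3
STACK	GG/UU	-0.3
STACK	GU/UG	-0.3
STACK	UA/GU	-1.3
STACK	UU/GA	-1.3
STACK	UC/GG	-1.3
STACK	UG/GC	-1.3
STACK	UG/GU	-0.3
STACK	UU/GG	-0.3
HAIRPIN	3	5.4
HAIRPIN	4	5.6
HAIRPIN	5	5.7
HAIRPIN	6	5.8
HAIRPIN	7	5.9
HAIRPIN	8	6
HAIRPIN	9	6.1
HAIRPIN	10	6.21
HAIRPIN	11	6.32
HAIRPIN	12	6.41
HAIRPIN	13	6.5
HAIRPIN	14	6.58
HAIRPIN	15	6.65
HAIRPIN	16	6.72
HAIRPIN	17	6.79
HAIRPIN	18	6.85
HAIRPIN	19	6.91
HAIRPIN	20	6.96
HAIRPIN	21	7.01
HAIRPIN	22	7.06
HAIRPIN	23	7.11
HAIRPIN	24	7.16
HAIRPIN	25	7.2
HAIRPIN	26	7.24
HAIRPIN	27	7.28
HAIRPIN	28	7.32
HAIRPIN	29	7.36
HAIRPIN	30	7.4
BULGE	1	3.8
BULGE	2	3.55
BULGE	3	3.98
BULGE	4	4.3
BULGE	5	4.54
BULGE	6	4.73
BULGE	7	4.9
BULGE	8	5.04
BULGE	9	5.17
BULGE	10	5.28
BULGE	11	5.39
BULGE	12	5.48
BULGE	13	5.57
BULGE	14	5.65
BULGE	15	5.72
BULGE	16	5.79
BULGE	17	5.86
BULGE	18	5.92
BULGE	19	5.98
BULGE	20	6.03
BULGE	21	6.08
BULGE	22	6.13
BULGE	23	6.18
BULGE	24	6.23
BULGE	25	6.27
BULGE	26	6.31
BULGE	27	6.35
BULGE	28	6.39
BULGE	29	6.43
BULGE	30	6.47
INTERNAL	2	1.8
INTERNAL	3	2.24
INTERNAL	4	2.55
INTERNAL	5	2.79
INTERNAL	6	2.98
INTERNAL	7	3.15
INTERNAL	8	3.3
INTERNAL	9	3.42
INTERNAL	10	3.54
INTERNAL	11	3.64
INTERNAL	12	3.73
INTERNAL	13	3.82
INTERNAL	14	3.9
INTERNAL	15	3.97
INTERNAL	16	4.04
INTERNAL	17	4.11
INTERNAL	18	4.17
INTERNAL	19	4.23
INTERNAL	20	4.28
INTERNAL	21	4.34
INTERNAL	22	4.39
INTERNAL	23	4.43
INTERNAL	24	4.48
INTERNAL	25	4.52
INTERNAL	26	4.57
INTERNAL	27	4.61
INTERNAL	28	4.65
INTERNAL	29	4.68
INTERNAL	30	4.72
INIT	-	4.1
AU_END	-	0.5
MULTI	a	3.4
MULTI	b	0.4
MULTI	c	0.1
META	max_loop	30
META	duplex_max_loop	6
META	min_hairpin	3
META	extrapolate	1
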