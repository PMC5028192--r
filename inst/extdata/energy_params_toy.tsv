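kind	key	kcal_per_mol
STACK	AA/UU	-3
STACK	AU/UA	-3
STACK	AC/UG	-3
STACK	AG/UC	-3
STACK	UA/AU	-3
STACK	UU/AA	-3
STACK	UC/AG	-3
STACK	UG/AC	-3
STACK	CA/GU	-3
STACK	CU/GA	-3
STACK	CC/GG	-3
STACK	CG/GC	-3
STACK	GA/CU	-3
STACK	GU/CA	-3
STACK	GC/CG	-3
STACK	GG/CC	-3
HAIRPIN	3	5
INIT	-	4
AU_END	-	0
META	max_loop	30
META	duplex_max_loop	6
META	min_hairpin	3
META	extrapolate	0
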