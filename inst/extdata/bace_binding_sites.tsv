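bace1_resnum	bace1_resname	bace1_status	bace2_resnum	bace2_resname	bace2_status
10	SER	CONSERVED	NA	NA	NA
11	GLY	CONSERVED	NA	NA	NA
12	GLN	CONSERVED	NA	NA	NA
13	GLY	CONSERVED	NA	NA	NA
30	LEU	CONSERVED	46	LEU	CONSERVED
32	ASP	CONSERVED	48	ASP	CONSERVED
34	GLY	CONSERVED	50	GLY	CONSERVED
35	SER	CONSERVED	51	SER	CONSERVED
69	VAL	CONSERVED	85	VAL	CONSERVED
70	PRO	GROUP_SPECIFIC	86	LYS	GROUP_SPECIFIC
71	TYR	CONSERVED	87	TYR	CONSERVED
72	THR	CONSERVED	88	THR	CONSERVED
73	GLN	CONSERVED	89	GLN	CONSERVED
NA	NA	NA	90	GLN	CONSERVED
108	PHE	CONSERVED	124	PHE	CONSERVED
110	ILE	GROUP_SPECIFIC	126	LEU	GROUP_SPECIFIC
115	TRP	CONSERVED	131	TRP	CONSERVED
118	ILE	CONSERVED	134	ILE	CONSERVED
126	ILE	GROUP_SPECIFIC	142	LEU	GROUP_SPECIFIC
198	TYR	CONSERVED	211	TYR	CONSERVED
224	LYS	CONSERVED	NA	NA	NA
226	ILE	CONSERVED	239	ILE	CONSERVED
228	ASP	CONSERVED	241	ASP	CONSERVED
230	GLY	CONSERVED	243	GLY	CONSERVED
231	THR	CONSERVED	244	THR	CONSERVED
232	THR	CONSERVED	245	THR	CONSERVED
233	ASN	GROUP_SPECIFIC	246	LEU	GROUP_SPECIFIC
235	ARG	CONSERVED	248	ARG	CONSERVED
329	THR	CONSERVED	NA	NA	NA
NA	NA	NA	337	SER	CONSERVED
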