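locus_tag	annotation	orf_position	reference	variants	aa_change
Francci3_0398	putative DNA-binding protein	452	G	G/A	Arg -> Gln
Francci3_1612	NLP/P60	356	G	G/A	Arg -> Gln
Francci3_1612	NLP/P60	375	A	A/C	Gln -> His
Francci3_1959	Transposase, IS110	1109	G	G/A	Gly -> Asp
Francci3_2025	Transposase, IS4	81	G	A/G	-
Francci3_2025	Transposase, IS4	91	C	C/T	Arg -> Cys
Francci3_2025	Transposase, IS4	119	T	T/C	Val -> Ala
Francci3_2063	hypothetical	310	A	A/C	Met -> Leu
Francci3_2063	hypothetical	313	C	C/T	Pro -> Ser
Francci3_2063	hypothetical	333	C	C/T	-
Francci3_2063	hypothetical	353	A	A/G	Glu -> Gly
Francci3_3047	Radical SAM	93	G	G/C	-
Francci3_3251	putative signal transduction histidine kinase	293	T	C/T	Val -> Ala
Francci3_3418	SsgA	165	C	T/C	-
Francci3_4082	dnaE	3579	T	C/T	-
Francci3_4082	dnaE	3601	G	G/A	Glu -> Lys
Francci3_4107	Integrase	135	C	C/T	-
Francci3_4124	Recombinase	162	T	T/A	-
Francci3_4124	Recombinase	168	C	T/C	-
Francci3_4157	Hypothetical	36	C	C/T	-
Francci3_4157	Hypothetical	49	A	A/G	Ser -> Gly
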