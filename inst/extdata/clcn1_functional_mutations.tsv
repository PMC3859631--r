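label	position	wt	mut	section	effect	sec_struct	rsa_printed	dv_printed	charge_printed	polarity_printed	contacts_printed	localization_printed	divergence
p.(Leu283Phe)	283	LEU	PHE	interface	pronounced_DN	alpha-helix H	7	23	No	No	No
p.(Ile290Met)	290	ILE	MET	interface	pronounced_DN	alpha-helix H	7	-4	No	No	No
p.(Glu291Lys)	291	GLU	LYS	interface	no_DN	alpha-helix H	9	30	Yes	No	H-bonds: Glu(OE1)-Ser541(N), Glu(OE2)-Val540(N)
p.(Glu291Asp)	291	GLU	ASP	interface	pronounced_DN	alpha-helix H	9	-27	No	No	H-bonds: Glu(OE1)-Ser541(N), Glu(OE2)-Val540(N)
p.(Phe297Ser)	297	PHE	SER	interface	pronounced_DN	beta-strand 1	9	-101	No	Yes	No
p.(Tyr302His)	302	TYR	HIS	interface	pronounced_DN	alpha-helix I	9	-35	Yes	Yes	No		dv
p.(Trp303Arg)	303	TRP	ARG	interface	pronounced_DN	alpha-helix I	8	-54	Yes	Yes	Clashes
p.(Phe306Leu)	306	PHE	LEU	interface	pronounced_DN	alpha-helix I	2	-23	No	No	No
p.(Phe307Ser)	307	PHE	SER	interface	pronounced_DN	alpha-helix I	13	-101	No	Yes	No
p.(Thr310Met)	310	THR	MET	interface	pronounced_DN	alpha-helix I	7	47	No	Yes	No
p.(Ala313Thr)	313	ALA	THR	interface	pronounced_DN	alpha-helix I	4	28	No	No	No
p.(Ala313Val)	313	ALA	VAL	interface	pronounced_DN	alpha-helix I	4	51	No	Yes	No
p.(Arg317Gln)	317	ARG	GLN	interface	pronounced_DN	alpha-helix I	59				No
p.(Gln552Arg)	552	GLN	ARG	interface	pronounced_DN	turn	40				No
p.(Ile553Phe)	553	ILE	PHE	interface	weak_DN	turn	0	23	No	No	No
p.(His555Asn)	555	HIS	ASN	interface	pronounced_DN	turn	16				No
p.(Ile556Asn)	556	ILE	ASN	interface	weak_DN	alpha-helix Q	0	-53	Yes	Yes	No		charge
p.(Gly230Glu)	230	GLY	GLU	pore	weak_DN	turn	0	78	Yes	Yes	No
p.(Gly233Ser)	233	GLY	SER	pore	no_DN	alpha-helix F	0	29	No	No	No
p.(Arg421Cys)	421	ARG	CYS	pore	weak_DN	alpha-helix L	29				H-bond: Arg(NH2)-Phe279(O)
p.(Phe428Ser)	428	PHE	SER	pore	no_DN	alpha-helix L	20				Interaction of aromatic rings: Phe428-Phe351
p.(Met485Val)	485	MET	VAL	pore	no_DN	alpha-helix N	10	23	No	No	No		dv
p.(Thr550Met)	550	THR	MET	pore	pronounced_DN	turn	47				No
p.(Glu291Gln)	291	GLU	GLN	novel		alpha-helix H	9	5	Yes	No	H-bonds: Glu(OE1)-Ser541(N), Glu(OE2)-Val540(N)	Dimer interface
p.(Tyr302Cys)	302	TYR	CYS	novel		alpha-helix I	9	-85	No	Yes	No	Dimer interface
p.(Thr432Arg)	432	THR	ARG	novel		turn					-	On the surface
p.(Asn455Tyr)	455	ASN	TYR	novel		turn					-	On the surface
p.(Gly482Glu)	482	GLY	GLU	novel		turn	7	78	Yes	Yes	No	Channel
p.(Ala493Val)	493	ALA	VAL	novel		alpha-helix N	1	51	No	Yes	No	Inside, but outside the channel and dimer interface
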