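res	atom	element	sidechain	polar	antecedent	ring
ALL	N	N	0	1	CA	0
ALL	CA	C	0	0		0
ALL	C	C	0	0		0
ALL	O	O	0	1	C	0
ALL	OXT	O	0	1	C	0
ALA	CB	C	1	0		0
ARG	CB	C	1	0		0
ARG	CG	C	1	0		0
ARG	CD	C	1	0		0
ARG	NE	N	1	1	CD	0
ARG	CZ	C	1	0		0
ARG	NH1	N	1	1	CZ	0
ARG	NH2	N	1	1	CZ	0
ASN	CB	C	1	0		0
ASN	CG	C	1	0		0
ASN	OD1	O	1	1	CG	0
ASN	ND2	N	1	1	CG	0
ASP	CB	C	1	0		0
ASP	CG	C	1	0		0
ASP	OD1	O	1	1	CG	0
ASP	OD2	O	1	1	CG	0
CYS	CB	C	1	0		0
CYS	SG	S	1	0	CB	0
GLN	CB	C	1	0		0
GLN	CG	C	1	0		0
GLN	CD	C	1	0		0
GLN	OE1	O	1	1	CD	0
GLN	NE2	N	1	1	CD	0
GLU	CB	C	1	0		0
GLU	CG	C	1	0		0
GLU	CD	C	1	0		0
GLU	OE1	O	1	1	CD	0
GLU	OE2	O	1	1	CD	0
HIS	CB	C	1	0		0
HIS	CG	C	1	0		1
HIS	ND1	N	1	1	CG	1
HIS	CD2	C	1	0		1
HIS	CE1	C	1	0		1
HIS	NE2	N	1	1	CD2	1
ILE	CB	C	1	0		0
ILE	CG1	C	1	0		0
ILE	CG2	C	1	0		0
ILE	CD1	C	1	0		0
LEU	CB	C	1	0		0
LEU	CG	C	1	0		0
LEU	CD1	C	1	0		0
LEU	CD2	C	1	0		0
LYS	CB	C	1	0		0
LYS	CG	C	1	0		0
LYS	CD	C	1	0		0
LYS	CE	C	1	0		0
LYS	NZ	N	1	1	CE	0
MET	CB	C	1	0		0
MET	CG	C	1	0		0
MET	SD	S	1	0	CG	0
MET	CE	C	1	0		0
PHE	CB	C	1	0		0
PHE	CG	C	1	0		1
PHE	CD1	C	1	0		1
PHE	CD2	C	1	0		1
PHE	CE1	C	1	0		1
PHE	CE2	C	1	0		1
PHE	CZ	C	1	0		1
PRO	CB	C	1	0		0
PRO	CG	C	1	0		0
PRO	CD	C	1	0		0
SER	CB	C	1	0		0
SER	OG	O	1	1	CB	0
THR	CB	C	1	0		0
THR	OG1	O	1	1	CB	0
THR	CG2	C	1	0		0
TRP	CB	C	1	0		0
TRP	CG	C	1	0		0
TRP	CD1	C	1	0		0
TRP	CD2	C	1	0		1
TRP	NE1	N	1	1	CD1	0
TRP	CE2	C	1	0		1
TRP	CE3	C	1	0		1
TRP	CZ2	C	1	0		1
TRP	CZ3	C	1	0		1
TRP	CH2	C	1	0		1
TYR	CB	C	1	0		0
TYR	CG	C	1	0		1
TYR	CD1	C	1	0		1
TYR	CD2	C	1	0		1
TYR	CE1	C	1	0		1
TYR	CE2	C	1	0		1
TYR	CZ	C	1	0		1
TYR	OH	O	1	1	CZ	0
VAL	CB	C	1	0		0
VAL	CG1	C	1	0		0
VAL	CG2	C	1	0		0
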