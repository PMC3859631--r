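res	code1	volume	polarity_class	charge_class	max_asa_tien	max_asa_miller
ALA	A	88.6	polar	neutral	129.0	113.0
ARG	R	173.4	very_polar	positive	274.0	241.0
ASN	N	114.1	very_polar	neutral	195.0	158.0
ASP	D	111.1	very_polar	negative	193.0	151.0
CYS	C	108.5	nonpolar	neutral	167.0	140.0
GLN	Q	143.8	very_polar	neutral	225.0	189.0
GLU	E	138.4	very_polar	negative	223.0	183.0
GLY	G	60.1	polar	neutral	104.0	85.0
HIS	H	153.2	very_polar	positive	224.0	194.0
ILE	I	166.7	nonpolar	neutral	197.0	182.0
LEU	L	166.7	nonpolar	neutral	201.0	180.0
LYS	K	168.6	very_polar	positive	236.0	211.0
MET	M	162.9	nonpolar	neutral	224.0	204.0
PHE	F	189.9	nonpolar	neutral	240.0	218.0
PRO	P	112.7	polar	neutral	159.0	143.0
SER	S	89.0	polar	neutral	155.0	122.0
THR	T	116.1	polar	neutral	172.0	146.0
TRP	W	227.8	nonpolar	neutral	285.0	259.0
TYR	Y	193.6	polar	neutral	263.0	229.0
VAL	V	140.0	nonpolar	neutral	174.0	160.0
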