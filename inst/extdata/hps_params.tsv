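# Hydropathy-scale (HPS) residue parameters.
# Columns: residue  mass(amu)  charge(e)  sigma(A)  lambda  eps(kcal/mol)
# Amino-acid rows carry the published hydropathy-scale values (normalised
# Kapcha-Rossky lambdas, vdW-volume sigmas, uniform 0.2 kcal/mol depth).
# R* rows are one-bead-per-nucleotide RNA beads with representative values
# (larger bond lengths and radii than amino acids); substitute your own
# calibration by editing this file.
residue	mass	charge	sigma	lambda	eps
ALA	71.08	0	5.04	0.730	0.2
ARG	156.19	1	6.56	0.000	0.2
ASN	114.10	0	5.68	0.432	0.2
ASP	115.09	-1	5.58	0.378	0.2
CYS	103.14	0	5.48	0.595	0.2
GLN	128.13	0	6.02	0.514	0.2
GLU	129.12	-1	5.92	0.459	0.2
GLY	57.05	0	4.50	0.649	0.2
HIS	137.14	0	6.08	0.514	0.2
ILE	113.16	0	6.18	0.973	0.2
LEU	113.16	0	6.18	0.973	0.2
LYS	128.17	1	6.36	0.514	0.2
MET	131.19	0	6.18	0.838	0.2
PHE	147.18	0	6.36	1.000	0.2
PRO	97.12	0	5.56	1.000	0.2
SER	87.08	0	5.18	0.595	0.2
THR	101.10	0	5.62	0.676	0.2
TRP	186.21	0	6.78	0.946	0.2
TYR	163.18	0	6.46	0.865	0.2
VAL	99.07	0	5.86	0.892	0.2
RA	329.2	-1	9.0	0.60	0.2
RC	305.2	-1	9.0	0.60	0.2
RG	345.2	-1	9.0	0.60	0.2
RU	306.2	-1	9.0	0.60	0.2
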