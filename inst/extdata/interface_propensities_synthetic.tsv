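# Amino-acid protein-protein interface propensities. SYNTHETIC STAND-IN:
# a constructed scale spanning the 0-2.21 range of published interface
# propensity scales, ordered as in the literature (aromatic / large
# hydrophobic residues enriched at interfaces, small polar and charged
# residues depleted). Replace with any published 20-value scale via the
# `table`/`path` arguments of lookup_pc()/jet_propensities().
aa3	propensity
ALA	0.65
ARG	1.10
ASN	0.90
ASP	0.45
CYS	1.40
GLN	0.75
GLU	0.30
GLY	0.70
HIS	1.20
ILE	1.44
LEU	1.35
LYS	0.00
MET	2.21
PHE	1.80
PRO	0.55
SER	0.60
THR	0.80
TRP	2.10
TYR	1.65
VAL	1.00
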