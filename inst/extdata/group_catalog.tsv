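# Default functional-group catalog: name <TAB> SMARTS
# Patterns use Open Babel SMARTS semantics; hydrogens are explicit atoms.
name	smarts
hydroxyl	[OX2H]
alcohol_aliphatic	[CX4][OX2H]
phenol	c[OX2H]
carboxylic_acid	[CX3](=O)[OX2H]
ester	[CX3](=O)[OX2H0][#6]
ketone	[#6][CX3](=O)[#6]
aldehyde	[CX3H1]=O
ether	[OD2]([#6])[#6]
carbonyl	[CX3]=[OX1]
primary_amine	[NX3H2][#6]
secondary_amine	[NX3H1]([#6])[#6]
tertiary_amine	[NX3]([#6])([#6])[#6]
amide	[NX3][CX3]=[OX1]
nitrile	[NX1]#[CX2]
imine	[CX3]=[NX2]
cc_triple_bond	C#C
cc_double_bond	C=C
aromatic_cc_bond	c:c
aromatic_ring	[aR]
heteroaromatic_atom	[a;!c]
aromatic_nitrogen	n
aromatic_oxygen	o
aromatic_sulfur	s
thiol	[SX2H]
thioether	[SX2]([#6])[#6]
disulfide	[SX2][SX2]
fluoro	[F]
chloro	[Cl]
bromo	[Br]
iodo	[I]
halide_on_carbon	[#6][F,Cl,Br,I]
gold_thiolate	[S][Au]
methyl	[CX4H3]
methylene	[CX4H2]
quaternary_carbon	[CX4]([#6])([#6])([#6])[#6]
terminal_alkyne	[CX2H1]#[CX2]
vinyl	[CX3H2]=[CX3]
allylic_alcohol	[CX3]=[CX3][CX4][OX2H]
ring3	[r3]
ring4	[r4]
ring5	[r5]
ring6	[r6]
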