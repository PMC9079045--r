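# Functional-group SMARTS pattern set bundled for testing and examples.
# Two columns: feature name, SMARTS. Covers the descriptor classes that
# dominate substructure-count models of ER-alpha inhibition (phenols,
# amines, aromatics, carboxylic-acid derivatives, ethers, tautomerizable
# motifs) plus a few deliberately rare elements. The full 307-pattern
# functional-group classification list is an external artifact and can be
# supplied by the user in the same format.
phenol	[OX2H]c
catechol	[OX2H]cc[OX2H]
hydroxyl	[OX2H]
aliphatic_hydroxyl	[OX2H][CX4]
primary_amine	[NX3;H2]
secondary_amine	[NX3;H1]
tertiary_amine	[NX3;H0]
primary_aliphatic_amine	[NX3;H2][CX4]
tertiary_aliphatic_amine	[NX3;H0]([CX4])([CX4])[CX4]
quaternary_ammonium	[NX4+]
aromatic_nitrogen	n
hetero_n_nonbasic	[nX3]
aromatic_atom	a
aromatic_carbon	c
carboxylic_acid	[CX3](=O)[OX2H]
ester	[CX3](=O)[OX2H0]
carboxylic_acid_derivative	[CX3](=[OX1])[#7,#8,#16]
amide	[NX3][CX3]=[OX1]
ketone	[#6][CX3](=[OX1])[#6]
aldehyde	[CX3H1]=[OX1]
ether	[OX2H0]([#6])[#6]
alkyl_aryl_ether	[OX2H0](c)[CX4]
diaryl_ether	c[OX2H0]c
c_ons_bond	[#6]~[#7,#8,#16]
halogen	[F,Cl,Br,I]
chlorine	[#17]
iodine	[#53]
phosphorus	[#15]
nitro_oxygen	[#7X3]~[OX1]
sulfonamide	[SX4](=[OX1])(=[OX1])[NX3]
sulfonyl	[SX4](=[OX1])=[OX1]
thioether	[SX2]([#6])[#6]
conjugated_carbonyl	[#6]=[#6]-[CX3]=[OX1]
conjugated_double_bond	[#6]=[#6]-[#6]=[#6]
alkene	[CX3]=[CX3]
alkyne	[CX2]#[CX2]
nitrile	[NX1]#[CX2]
tertiary_carbon	[CX4H1]([#6])([#6])[#6]
secondary_carbon	[CX4H2]([#6])[#6]
imine	[CX3]=[NX2]
tautomerizable_1_3	[CX4;!H0][CX3]=[OX1]
ring_atom	[R]
aliphatic_ring_carbon	[C;R]
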