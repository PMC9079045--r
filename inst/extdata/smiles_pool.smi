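# Bundled pool of drug-like SMILES used as default structures by the
# synthetic activity-table generator. One record per line: SMILES <tab> name.
CC(=O)Oc1ccccc1C(=O)O	aspirin
CC(=O)Nc1ccc(O)cc1	paracetamol
CC(C)Cc1ccc(cc1)C(C)C(=O)O	ibuprofen
Cn1cnc2c1c(=O)n(C)c(=O)n2C	caffeine
CN1CCC[C@H]1c1cccnc1	nicotine
C[C@]12CC[C@H]3[C@@H](CCc4cc(O)ccc34)[C@@H]1CC[C@@H]2O	estradiol
CCC(=C(c1ccccc1)c1ccc(OCCN(C)C)cc1)c1ccccc1	tamoxifen
CCC(=C(CC)c1ccc(O)cc1)c1ccc(O)cc1	diethylstilbestrol
COc1ccc2cc(ccc2c1)[C@@H](C)C(=O)O	naproxen
CC(C)(C)NCC(O)c1ccc(O)c(CO)c1	salbutamol
CC(C)NCC(O)COc1cccc2ccccc12	propranolol
CC(C)NCC(O)COc1ccc(CC(N)=O)cc1	atenolol
COCCc1ccc(OCC(O)CNC(C)C)cc1	metoprolol
OC(=O)Cc1ccccc1Nc1c(Cl)cccc1Cl	diclofenac
Cc1cccc(C)c1Nc1ccccc1C(=O)O	mefenamic_acid
CC(=O)CC(c1ccccc1)c1c(O)c2ccccc2oc1=O	warfarin
O=c1ccc2ccccc2o1	coumarin
Oc1cc(O)c2c(c1)oc(-c1ccc(O)c(O)c1)c(O)c2=O	quercetin
Oc1ccc(/C=C/c2cc(O)cc(O)c2)cc1	resveratrol
NCCc1ccc(O)c(O)c1	dopamine
NCCc1c[nH]c2ccccc12	tryptamine
NCCc1c[nH]cn1	histamine
CNC[C@H](O)c1ccc(O)c(O)c1	adrenaline
CC(N)Cc1ccccc1	amphetamine
CNCCC(Oc1ccc(cc1)C(F)(F)F)c1ccccc1	fluoxetine
CN1C(=O)CN=C(c2ccccc2)c2cc(Cl)ccc21	diazepam
Cn1c(=O)c2[nH]cnc2n(C)c1=O	theophylline
NC(=O)c1cccnc1	nicotinamide
NNC(=O)c1ccncc1	isoniazid
Nc1ccc(cc1)S(N)(=O)=O	sulfanilamide
CN(C)CCCN1c2ccccc2Sc2ccc(Cl)cc21	chlorpromazine
CN(C)CCCN1c2ccccc2CCc2ccccc21	imipramine
CCN(CC)CC(=O)Nc1c(C)cccc1C	lidocaine
CCN(CC)CCOC(=O)c1ccc(N)cc1	procaine
CCOC(=O)c1ccc(N)cc1	benzocaine
CC(C(=O)O)c1cccc(c1)C(=O)c1ccccc1	ketoprofen
Cc1ccc(C)c(OCCCC(C)(C)C(=O)O)c1	gemfibrozil
O=C1NC(=O)C(N1)(c1ccccc1)c1ccccc1	phenytoin
COc1ccc2[nH]cc(CCNC(C)=O)c2c1	melatonin
N[C@@H](Cc1c[nH]c2ccccc12)C(=O)O	tryptophan
N[C@@H](Cc1ccc(O)cc1)C(=O)O	tyrosine
OC[C@H](O)[C@H]1OC(=O)C(O)=C1O	ascorbic_acid
CC(C)[C@@H]1CC[C@@H](C)C[C@H]1O	menthol
COc1cc(C=O)ccc1O	vanillin
C=CCc1ccc(O)c(OC)c1	eugenol
Cc1ccc(C(C)C)c(O)c1	thymol
O=C/C=C/c1ccccc1	cinnamaldehyde
NC(=O)c1ccccc1	benzamide
CC(=O)c1ccccc1	acetophenone
Oc1ccc(cc1)[N+](=O)[O-]	nitrophenol
NS(=O)(=O)c1cc(C(=O)O)c(NCc2ccco2)cc1Cl	furosemide
Oc1cc(Cl)ccc1Oc1ccc(Cl)cc1Cl	triclosan
CC(C)(c1ccc(O)cc1)c1ccc(O)cc1	bisphenol_a
Oc1ccc(cc1)-c1coc2cc(O)cc(O)c2c1=O	genistein
CCCCCCCCc1ccc(O)cc1	octylphenol
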