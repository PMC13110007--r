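rule	smarts	family
rhodanine	O=C1CSC(=S)N1	A
ene_rhodanine	O=C1C(=[#6])SC(=S)N1	A
thiazolidinone_ene	O=C1C(=[#6])SC(=[!S])N1	A
para_quinone	O=C1C=CC(=O)C=C1	A
ortho_quinone	O=C1C(=O)C=CC=C1	A
catechol	[OX2H]c1ccccc1[OX2H]	B
hydroxyphenyl_hydrazone	[OX2H]c1ccccc1[CH]=N[NX3]	A
aryl_azo	cN=Nc	B
alkylidene_barbiturate	O=C1NC(=O)NC(=O)C1=[#6]	A
isothiazolone	O=C1C=CSN1	B
acyl_hydrazone	[#6]C(=O)N[NX2]=[CH][#6]	B
thiourea	[NX3][CX3](=S)[NX3]	C
beta_keto_anhydride	O=C1OC(=O)C(=[#6])C1	C
mannich_phenol	[OX2H]c1ccccc1[CH2][NX3]	C
ene_one_dienone	O=C([#6]=[#6])[#6]=[#6]	C
imine_imine	C=NN=C	B
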