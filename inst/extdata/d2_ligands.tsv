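id	activity_class	amine_config_policy	smiles
(R)-NPA	full	enumerate	CCC[NH+]1CCC2=CC=CC3=C2[C@H]1CC4=C3C(=C(C=C4)O)O
talipexole	full	enumerate	NC1=NC2=C(S1)CC[NH+](CC=C)CC2
sumanirole	full	fixed	C[NH2+][C@@H]1CC2=CC=CC3=C2N(C1)C(=O)N3
(R,R)-PHNO	full	fixed	CCC[NH+]1CCO[C@@H]2Cc3ccc(O)cc3C[C@@H]12
nPr-DHX	full	enumerate	C1CC2=CC=CC=C2[C@@H]3[C@H]1[NH+](CCC)CC4=CC(=C(C=C43)O)O
(3S,9R)-6a	full	enumerate	CCC[NH+]1CCC[C@@H]2CCc3c(O)cccc3[C@@H]12
quinpirole	full	enumerate	CCC[NH+]1CC[C@@H]2[C@H](C1)CC3=C(C2)C=NN3
(S)-5-OH-DPAT	full	fixed	CCC[NH+](CCC)[C@H]1CCc2c(O)cccc2C1
(S)-DPAT	full	fixed	CCC[NH+](CCC)[C@H]1CCc2ccccc2C1
(R)-3-PPP	full	enumerate	CCC[NH+]1CCC[C@@H](C1)c1cccc(O)c1
apomorphine	full	enumerate	C[NH+]1CCC2=CC=CC3=C2[C@H]1CC4=C3C(=C(C=C4)O)O
dopamine	full	fixed	[NH3+]CCc1ccc(O)c(O)c1
A70108	full	fixed	[NH3+]C[C@@H]1O[C@@H](c2ccccc2)Cc2c(O)c(O)ccc21
(R)-5-OH-DPAT	partial	fixed	CCC[NH+](CCC)[C@@H]1CCc2c(O)cccc2C1
(S)-3-PPP	partial	enumerate	CCC[NH+]1CCC[C@H](C1)c1cccc(O)c1
(S)-6-OH-DPAT	partial	fixed	CCC[NH+](CCC)[C@H]1CCc2cc(O)ccc2C1
(R)-7-OH-DPAT	partial	fixed	CCC[NH+](CCC)[C@@H]1CCc2ccc(O)cc2C1
DHX	partial	fixed	C1CC2=CC=CC=C2[C@@H]3[C@H]1[NH2+]CC4=CC(=C(C=C43)O)O
(S)-sumanirole	inactive	fixed	C[NH2+][C@H]1CC2=CC=CC3=C2N(C1)C(=O)N3
(S,S)-PHNO	inactive	enumerate	CCC[NH+]1CCO[C@H]2Cc3ccc(O)cc3C[C@H]12
(3R,9S)-6b	inactive	enumerate	CCC[NH+]1CCC[C@H]2CCc3c(O)cccc3[C@H]12
(S)-7-OH-DPAT	inactive	fixed	CCC[NH+](CCC)[C@H]1CCc2ccc(O)cc2C1
doxanthrine	inactive	fixed	C1OC2=CC=CC=C2[C@@H]3[C@H]1[NH2+]CC4=CC(=C(C=C43)O)O
A86929	inactive	fixed	CCC[NH+]1Cc2cc(O)c(O)cc2[C@H]2c3ccsc3CC[C@@H]12
A77636	inactive	fixed	[NH3+]C[C@@H]1O[C@@H](C23CC4CC(C2)CC(C4)C3)Cc2c(O)c(O)ccc21
A77641	inactive	fixed	[NH3+]C[C@H]1O[C@H](C23CC4CC(C2)CC(C4)C3)Cc2c(O)c(O)ccc21
A70360	inactive	fixed	[NH3+]C[C@H]1O[C@H](c2ccccc2)Cc2c(O)c(O)ccc21
SKF38393	inactive	fixed	OC1=C(O)C=C2CC[NH2+]CC(c3ccccc3)C2=C1
cis-DHX	inactive	fixed	C1CC2=CC=CC=C2[C@@H]3[C@@H]1[NH2+]CC4=CC(=C(C=C43)O)O
(-)-DHX	inactive	fixed	C1CC2=CC=CC=C2[C@H]3[C@@H]1[NH2+]CC4=CC(=C(C=C43)O)O
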