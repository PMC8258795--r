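# Demonstration compound set: the six approved repositioning candidates and
# the assay positive control. SMILES transcribed from the published chemical
# structures of these drugs (no database fetch); verify against an
# authoritative registry before production use. The two query tool compounds
# are deliberately absent (structures not reliably sourceable offline).
name,smiles,role,provenance
Vardenafil,CCCC1=NC(=C2N1N=C(NC2=O)C3=CC(=CC=C3OCC)S(=O)(=O)N4CCN(CC4)CC)C,hit,transcribed
Paroxetine,C1CNCC(C1c1ccc(F)cc1)COc1ccc2c(c1)OCO2,hit,transcribed
Efavirenz,C1CC1C#CC2(C3=CC(=CC=C3NC(=O)O2)Cl)C(F)(F)F,hit,transcribed
Crizotinib,CC(c1c(Cl)ccc(F)c1Cl)Oc1cc(-c2cnn(C3CCNCC3)c2)cnc1N,hit,transcribed
Liothyronine,NC(Cc1cc(I)c(Oc2ccc(O)c(I)c2)c(I)c1)C(=O)O,hit,transcribed
Sunitinib,CCN(CC)CCNC(=O)c1c(C)[nH]c(/C=C2\C(=O)Nc3ccc(F)cc23)c1C,hit,transcribed
GW5074,Oc1c(Br)cc(/C=C2\C(=O)Nc3ccc(I)cc23)cc1Br,control,transcribed
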