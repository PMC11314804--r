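band_cm1,vibrational_mode,assignment
674,nu(C-C-O) + delta(C-C-O),"Carbohydrates, Glycerol"
695,delta(C-C-H) twisting,Cellulose Avicel (II)
704,ring deformation,Cytosine
713,C-S-C asymmetric stretch; H2O rocking,"Isoleucine, Methionine"
726,ring breath,Adenine
859,tau(C-N),"Arginine, Serine"
952,"delta(CCH), delta(COH)",Pectin
976,CH2 rocking,Glycerol
1019,C-O-H deformation,Alcoholic hydroxyl
1114,nus(C-O-C),"Glycosidic ring breathing, Cellulose"
1211,delta(>C=C-C-) beta-ring,beta-Carotene
1345,nu(C-O); delta(C-O-H),Carbohydrates
1400,nu; delta(C-OH)COOH; deltas(CH3),"Pectin, beta-Carotene, Cellulose"
1414,delta(C-H),Deoxyadenosine triphosphate
1426,nus(COO-); CH2 deformation,"Aspartic acid, Glutamic acid, Methionine"
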