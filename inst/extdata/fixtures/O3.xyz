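10
charge=1 O3 SMILES=C[OH+]C generator=rdkit-ETKDGv3+MMFF94 seed=2013
C      1.17906813     0.16540138    -0.09198698
O     -0.02048852     0.11940412     0.65025402
C     -1.18656376    -0.03642353    -0.12946367
H      2.01264575     0.32252778     0.59820574
H      1.33257909    -0.77827249    -0.62329215
H      1.15309550     0.99533874    -0.80374613
H      0.02606684    -0.56018223     1.37135703
H     -1.16124877    -0.99102708    -0.66281255
H     -2.05599557    -0.02460588     0.53375120
H     -1.27915869     0.78783919    -0.84226651
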