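11
charge=1 A8 SMILES=C[NH2+]C generator=rdkit-ETKDGv3+MMFF94 seed=2013
C      1.16834633     0.49775337     0.05194961
N     -0.03740386    -0.23718681     0.51796606
C     -1.13739579    -0.30149124    -0.48054553
H      1.89808853     0.47657441     0.86431201
H      1.56142911    -0.01155317    -0.83102863
H      0.87739279     1.52572301    -0.17648237
H     -0.38906816     0.20373819     1.37889433
H      0.23289730    -1.19404830     0.78373550
H     -1.95860089    -0.86028261    -0.02636529
H     -1.44985876     0.71902369    -0.71394129
H     -0.76582659    -0.81825054    -1.36849438
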