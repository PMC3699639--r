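8
charge=1 A2 SMILES=C[NH3+] generator=rdkit-ETKDGv3+MMFF94 seed=2013
C      0.75050497    -0.02894439     0.05587314
N     -0.71999618     0.02776782    -0.05360197
H      1.10727790     0.97680548     0.28567304
H      0.99898290    -0.72646367     0.85796641
H      1.14351446    -0.37567461    -0.90170174
H     -1.01575934     0.67318000    -0.79778591
H     -1.14896014     0.34989139     0.82393363
H     -1.11556457    -0.89656203    -0.27035660
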