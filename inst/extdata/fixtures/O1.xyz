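7
charge=1 O1 SMILES=C[OH2+] generator=rdkit-ETKDGv3+MMFF94 seed=2013
C     -0.56326065     0.03524742    -0.00178731
O      0.78770132    -0.34816169     0.00023141
H     -0.63285758     1.12568138     0.00623115
H     -1.04854677    -0.35708726    -0.89855460
H     -1.05505260    -0.37062049     0.88536129
H      1.25302175    -0.04873998     0.82287187
H      1.25899453    -0.03631938    -0.81435381
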