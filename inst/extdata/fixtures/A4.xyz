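14
charge=1 A4 SMILES=CCC[NH3+] generator=rdkit-ETKDGv3+MMFF94 seed=2013
C      1.91439871    -0.05693146    -0.12818547
C      0.49234169    -0.54965727     0.08557929
C     -0.51259584     0.57760854    -0.09028799
N     -1.88003210     0.04752771     0.12774554
H      2.62444072    -0.87963778     0.00190054
H      2.04225679     0.34581762    -1.13807644
H      2.16935869     0.72878778     0.59019827
H      0.28112863    -1.35720425    -0.62551956
H      0.40744658    -0.97664081     1.09199979
H     -0.49058621     0.99262557    -1.10226635
H     -0.36247073     1.37858919     0.63958628
H     -2.10937662    -0.69826745    -0.54274431
H     -2.58587035     0.78732505     0.01572985
H     -1.99043996    -0.33994244     1.07434056
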