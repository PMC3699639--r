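11
charge=1 A3 SMILES=CC[NH3+] generator=rdkit-ETKDGv3+MMFF94 seed=2013
C      1.20076790    -0.35730901    -0.04305557
C      0.05860269     0.63265118     0.02367295
N     -1.22652810    -0.10447210     0.02536625
H      1.18892958    -1.03385236     0.81790738
H      2.15928814     0.17090357    -0.04517090
H      1.14631973    -0.96362567    -0.95328815
H      0.09024049     1.22529451     0.94199987
H      0.04723973     1.29615958    -0.84533721
H     -2.02454915     0.54299516     0.07023659
H     -1.34010886    -0.67149127    -0.82551322
H     -1.30020216    -0.73725360     0.83318200
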