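5
charge=1 A1 SMILES=[NH4+] generator=rdkit-ETKDGv3+MMFF94 seed=2013
N      0.00000014    -0.00000006    -0.00000016
H      0.12777397    -0.33707722     0.96139944
H     -0.59902970    -0.65534290    -0.51567867
H     -0.44240038     0.92638575     0.01807681
H      0.91365598     0.06603443    -0.46379742
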