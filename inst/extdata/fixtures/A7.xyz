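17
charge=1 A7 SMILES=CC([NH3+])(C)C generator=rdkit-ETKDGv3+MMFF94 seed=2013
C     -0.60567361     1.10587300     0.87763438
C     -0.01528430    -0.01125450     0.01842522
N      0.84956190     0.62558983    -1.02412359
C      0.86797073    -0.93992901     0.85040967
C     -1.11290803    -0.79230689    -0.70265370
H      0.18058816     1.69190559     1.36708829
H     -1.25136120     0.69575223     1.66220462
H     -1.20973186     1.79551801     0.27704180
H      1.28068304    -0.07660159    -1.64074773
H      1.61395694     1.17059701    -0.60242554
H      0.31242310     1.26758493    -1.62286185
H      1.67906235    -0.38836715     1.33940627
H      1.32305212    -1.72064090     0.23025044
H      0.28433191    -1.43619070     1.63383299
H     -1.72550331    -0.13464777    -1.32988670
H     -1.77996322    -1.28234108     0.01537701
H     -0.69120472    -1.57054101    -1.34897156
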