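16
charge=1 O6 SMILES=CC[OH+]CC generator=rdkit-ETKDGv3+MMFF94 seed=2013
C      2.13563822    -0.38659535    -0.03469118
C      0.93074577    -0.05190093     0.82736603
O      0.02957537     0.80700337     0.14946383
C     -0.95370456     0.17873745    -0.65456980
C     -2.23253977    -0.01818733     0.13918808
H      2.83292065    -1.02251199     0.51962894
H      2.66963835     0.52092396    -0.33637376
H      1.84151038    -0.91857784    -0.94523651
H      1.26362929     0.47230063     1.72986028
H      0.42064307    -0.96506948     1.15236658
H      0.49727666     1.53769950    -0.33116163
H     -0.58996519    -0.77656891    -1.04707056
H     -1.15557429     0.82968057    -1.51265725
H     -2.07076596    -0.67563549     0.99986512
H     -2.61367188     0.93710430     0.51611064
H     -3.00535611    -0.46840246    -0.49158346
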