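12
charge=1 O10 SMILES=COC(=[OH+])C generator=rdkit-ETKDGv3+MMFF94 seed=2013
C      1.89477964    -0.22950375    -0.35922483
O      0.56641836    -0.74868586    -0.27171097
C     -0.34149692     0.13207805     0.18204553
O     -0.05850467     1.33829897     0.52933413
C     -1.72580178    -0.40265175     0.29344325
H      1.92599864     0.62108053    -1.04718052
H      2.25304659     0.06428273     0.63223262
H      2.54470720    -1.01830229    -0.74744200
H     -0.84980106     1.83165650     0.85075172
H     -2.43776092     0.36848959    -0.01064430
H     -1.91774176    -0.67220882     1.33498116
H     -1.85384332    -1.28453390    -0.33905890
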