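17
charge=1 A9 SMILES=CC[NH2+]CC generator=rdkit-ETKDGv3+MMFF94 seed=2013
C      2.37095815     0.00918150     0.10208456
C      0.95610583    -0.50074339     0.28806047
N      0.03858468     0.28838868    -0.59154855
C     -1.39014890    -0.15370508    -0.60347718
C     -2.08368374     0.23412708     0.68660240
H      2.69972562    -0.10471234    -0.93616034
H      3.06140769    -0.55260044     0.73886535
H      2.44809754     1.06801805     0.37028805
H      0.87359539    -1.55172369    -0.00465593
H      0.62785561    -0.36924861     1.32244833
H      0.39157680     0.23517149    -1.55727247
H      0.08661065     1.28521376    -0.33781733
H     -1.40859634    -1.23390629    -0.77730898
H     -1.85781061     0.35193859    -1.45398235
H     -3.14815020    -0.01460727     0.62788062
H     -1.99868727     1.30915089     0.87589748
H     -1.66744089    -0.29994293     1.54590351
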