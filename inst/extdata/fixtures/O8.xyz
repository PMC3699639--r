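11
charge=1 O8 SMILES=CC(=[OH+])C generator=rdkit-ETKDGv3+MMFF94 seed=2013
C      1.06298290    -0.70266196     0.07688764
C      0.02341698     0.34894178    -0.13361137
O      0.34204511     1.50190746    -0.61686305
C     -1.40582026     0.09189016     0.20923953
H      2.04558095    -0.33794988    -0.22860420
H      0.80261995    -1.58810026    -0.50868956
H      1.08702009    -0.97806899     1.13436822
H      1.30440873     1.59553069    -0.81822145
H     -1.48544208    -0.14842138     1.27237017
H     -1.77007917    -0.75892970    -0.37192753
H     -2.00673319     0.97586207    -0.01494839
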