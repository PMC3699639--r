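14
charge=1 A10 SMILES=C[NH+](C)C generator=rdkit-ETKDGv3+MMFF94 seed=2013
C      1.36076347    -0.23966713    -0.40455229
N      0.09314908     0.06962905     0.33961385
C     -0.58160323     1.30349681    -0.18818613
C     -0.83841707    -1.10812411     0.37669326
H      1.83273075    -1.10205719     0.07350745
H      2.01732553     0.63139496    -0.33252611
H      1.11050561    -0.45705354    -1.44640055
H      0.36015296     0.26921472     1.31308600
H     -1.45286124     1.50826764     0.43949989
H     -0.87871594     1.12333507    -1.22481474
H      0.12789123     2.13250569    -0.12205668
H     -1.14172201    -1.34645744    -0.64631010
H     -1.70267813    -0.83763572     0.98898382
H     -0.30652100    -1.94684882     0.83346232
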