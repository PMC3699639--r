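14
charge=1 O5 SMILES=C1C[OH+]CC1 generator=rdkit-ETKDGv3+MMFF94 seed=2013
C      1.13907706    -0.30743583    -0.12941144
C      0.60347958     1.11335582    -0.16453188
O     -0.68279589     1.04235859     0.43925730
C     -1.11259901    -0.30972830     0.54687505
C     -0.12968350    -1.11420848    -0.28663072
H      1.60627668    -0.51717879     0.84043308
H      1.87355853    -0.50178362    -0.91561196
H      1.23861549     1.80826728     0.39074063
H      0.49148192     1.47127516    -1.19396067
H     -1.34495825     1.60483284    -0.03923741
H     -1.06964652    -0.59739257     1.60260428
H     -2.14039522    -0.41585776     0.18882784
H     -0.02942749    -2.14687766     0.05821933
H     -0.44298338    -1.12962667    -1.33757340
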