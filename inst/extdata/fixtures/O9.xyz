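23
charge=1 O9 SMILES=CC(C)C(=[OH+])C(C)C generator=rdkit-ETKDGv3+MMFF94 seed=2013
C      1.67461549    -1.51605975     0.21961253
C      0.94627672    -0.32563352    -0.39222054
C      1.92043318     0.67316314    -1.00488178
C      0.10434235     0.35850206     0.66190171
O      0.66004675     0.87991817     1.70568507
C     -1.39862810     0.46685210     0.55388993
C     -2.04499945    -0.91205151     0.55839634
C     -1.79864600     1.28191985    -0.66874698
H      2.37610216    -1.20471580     1.00098120
H      2.24011982    -2.05927445    -0.54465555
H      0.96422371    -2.21411289     0.67564399
H      0.28762617    -0.69510326    -1.18499873
H      2.49478714     0.20877442    -1.81324079
H      1.38504515     1.53365752    -1.42058512
H      2.62987336     1.05531790    -0.26312143
H      1.64190043     0.78266451     1.72891366
H     -1.73531338     1.00514202     1.44868935
H     -1.78800555    -1.48499505    -0.33870677
H     -1.71559823    -1.49366037     1.42626824
H     -3.13592059    -0.82754966     0.60117376
H     -1.29471949     2.25456183    -0.67020845
H     -2.87907550     1.45985867    -0.67822629
H     -1.53448615     0.77282409    -1.60156335
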