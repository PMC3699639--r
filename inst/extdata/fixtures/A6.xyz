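17
charge=1 A6 SMILES=CCCC[NH3+] generator=rdkit-ETKDGv3+MMFF94 seed=2013
C      2.38000784     0.12487238     0.21064266
C      0.94898412    -0.37890348     0.32258104
C      0.02849186     0.33168124    -0.67207947
C     -1.39574955    -0.20973541    -0.67317190
N     -2.05958823     0.06019351     0.62377727
H      2.78191542    -0.05357717    -0.79183388
H      3.02143584    -0.39322936     0.93043695
H      2.43498023     1.19844874     0.41742170
H      0.93339239    -1.45923615     0.13786732
H      0.60046359    -0.21808171     1.34845909
H      0.43807966     0.21524821    -1.68312408
H      0.01689219     1.40792627    -0.45925394
H     -1.42607725    -1.29180875    -0.83130475
H     -1.99906061     0.28496655    -1.44009393
H     -3.04570013    -0.23171719     0.59936343
H     -2.04396601     1.06183847     0.85769221
H     -1.61450136    -0.44888613     1.39842793
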