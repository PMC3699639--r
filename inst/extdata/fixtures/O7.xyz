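17
charge=1 O7 SMILES=C[OH+]c1ccccc1 generator=rdkit-ETKDGv3+MMFF94 seed=2013
C     -2.55289072    -0.20797492    -0.15370110
O     -1.58844260     0.02107383     0.85065123
C     -0.24918740     0.06683625     0.39636604
C      0.36825627     1.30983237     0.22611384
C      1.69430829     1.37263205    -0.20222928
C      2.40243892     0.19878065    -0.45556751
C      1.78960997    -1.04149958    -0.28140222
C      0.46348952    -1.11284688     0.14711943
H     -2.46420953     0.53480296    -0.95240693
H     -3.54736067    -0.11686757     0.29303799
H     -2.44814967    -1.21591498    -0.56631199
H     -1.69443296    -0.58870375     1.62380378
H     -0.16281347     2.24034335     0.41935213
H      2.18210803     2.33670914    -0.34016866
H      3.43774405     0.25134724    -0.79068852
H      2.35345539    -1.95146577    -0.48325647
H      0.01607660    -2.09708437     0.26928825
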