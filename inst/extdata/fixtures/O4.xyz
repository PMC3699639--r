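13
charge=1 O4 SMILES=C[OH+]CC generator=rdkit-ETKDGv3+MMFF94 seed=2013
C      1.86466662     0.01519275     0.00762022
O      0.53529349    -0.40943264    -0.20663749
C     -0.44570615     0.37265139     0.45274402
C     -1.83108814    -0.07496185     0.02240266
H      2.53684134    -0.64141826    -0.55181332
H      1.99785593     1.03947477    -0.35162298
H      2.11523737    -0.04435168     1.07061975
H      0.42987226    -1.37428601    -0.00039029
H     -0.30627564     1.42856744     0.19660399
H     -0.33365128     0.25546338     1.53616612
H     -1.96144197     0.03189572    -1.05993404
H     -2.00424071    -1.12607347     0.27750688
H     -2.59736311     0.52727846     0.52023801
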