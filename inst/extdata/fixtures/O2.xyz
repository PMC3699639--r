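10
charge=1 O2 SMILES=CC[OH2+] generator=rdkit-ETKDGv3+MMFF94 seed=2013
C      1.10934239    -0.27254557    -0.02778211
C     -0.18121127     0.52154156    -0.05451242
O     -1.28611595    -0.34927419    -0.14212335
H      1.21547474    -0.88381928    -0.93054002
H      1.96991397     0.40088543     0.03196886
H      1.14191776    -0.94541572     0.83598503
H     -0.19791768     1.19049939    -0.92052746
H     -0.28198322     1.12583724     0.85239855
H     -2.13009942     0.14653343    -0.30016461
H     -1.35932132    -0.93424230     0.65529754
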