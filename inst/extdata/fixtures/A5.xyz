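14
charge=1 A5 SMILES=CC([NH3+])C generator=rdkit-ETKDGv3+MMFF94 seed=2013
C      1.38695477    -0.25412188    -0.31496207
C      0.09101643     0.06853861     0.41154822
N     -0.51219729     1.27707920    -0.21385487
C     -0.91420371    -1.06909543     0.32967781
H      1.87115143    -1.12901420     0.13148760
H      2.08973664     0.58386996    -0.25387201
H      1.21146159    -0.47023908    -1.37463894
H      0.29130916     0.32905015     1.45587152
H     -1.38388696     1.54968438     0.25993484
H     -0.73610584     1.12410860    -1.20652889
H      0.12432110     2.08383019    -0.16256994
H     -1.16415852    -1.31158306    -0.70913978
H     -1.84352610    -0.80912672     0.84798376
H     -0.51187270    -1.97298072     0.79906274
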