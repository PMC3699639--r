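# PM3 parameter set (Stewart, J. Comput. Chem. 10 (1989) 209) for H, C, N, O.
# Units: uss, upp, betas, betap, gss, gsp, gpp, gp2, hsp in eV;
# zs, zp in bohr^-1; alpha in A^-1; gauss rows are K (eV), L (A^-2), M (A);
# eheat (experimental atomic heat of formation) in kcal/mol.
element H
z 1
zcore 1
norb 1
npq 1
uss -13.073321
upp 0.0
zs 0.967807
zp 0.0
betas -5.626512
betap 0.0
alpha 3.356386
gss 14.794208
gsp 0.0
gpp 0.0
gp2 0.0
hsp 0.0
eheat 52.102
gauss 1.128750 5.096282 1.537465
gauss -1.060329 6.003788 1.570189

element C
z 6
zcore 4
norb 4
npq 2
uss -47.270320
upp -36.266918
zs 1.565085
zp 1.842345
betas -11.910015
betap -9.802755
alpha 2.707807
gss 11.200708
gsp 10.265027
gpp 10.796292
gp2 9.042566
hsp 2.290980
eheat 170.89
gauss 0.050107 6.003165 1.642214
gauss 0.050733 6.002979 0.892488

element N
z 7
zcore 5
norb 4
npq 2
uss -49.335672
upp -47.509736
zs 2.028094
zp 2.313728
betas -14.062521
betap -20.043848
alpha 2.830545
gss 11.904787
gsp 7.348565
gpp 11.754672
gp2 10.807277
hsp 1.136713
eheat 113.00
gauss 1.501674 5.901148 1.710740
gauss -1.505772 6.004658 1.716149

element O
z 8
zcore 6
norb 4
npq 2
uss -86.993002
upp -71.879580
zs 3.796544
zp 2.389402
betas -45.202651
betap -24.752515
alpha 3.217102
gss 15.755760
gsp 10.621160
gpp 13.654016
gp2 12.406095
hsp 0.593883
eheat 59.559
gauss -1.131128 6.002477 1.607311
gauss 1.137891 5.950512 1.598395
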