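# AM1 parameter set (Dewar, Zoebisch, Healy, Stewart, JACS 107 (1985) 3902)
# for H, C, N, O.  Units as in params_pm3.dat.
element H
z 1
zcore 1
norb 1
npq 1
uss -11.396427
upp 0.0
zs 1.188078
zp 0.0
betas -6.173787
betap 0.0
alpha 2.882324
gss 12.848
gsp 0.0
gpp 0.0
gp2 0.0
hsp 0.0
eheat 52.102
gauss 0.122796 5.000000 1.200000
gauss 0.005090 5.000000 1.800000
gauss -0.018336 2.000000 2.100000

element C
z 6
zcore 4
norb 4
npq 2
uss -52.028658
upp -39.614239
zs 1.808665
zp 1.685116
betas -15.715783
betap -7.719283
alpha 2.648274
gss 12.23
gsp 11.47
gpp 11.08
gp2 9.84
hsp 2.43
eheat 170.89
gauss 0.011355 5.000000 1.600000
gauss 0.045924 5.000000 1.850000
gauss -0.020061 5.000000 2.050000
gauss -0.001260 5.000000 2.650000

element N
z 7
zcore 5
norb 4
npq 2
uss -71.860000
upp -57.167581
zs 2.315410
zp 2.157940
betas -20.299110
betap -18.238666
alpha 2.947286
gss 13.59
gsp 12.66
gpp 12.98
gp2 11.59
hsp 3.14
eheat 113.00
gauss 0.025251 5.000000 1.500000
gauss 0.028953 5.000000 2.100000
gauss -0.005806 2.000000 2.400000

element O
z 8
zcore 6
norb 4
npq 2
uss -97.830000
upp -78.262380
zs 3.108032
zp 2.524039
betas -29.272773
betap -29.272773
alpha 4.455371
gss 15.42
gsp 14.48
gpp 14.52
gp2 12.98
hsp 3.94
eheat 59.559
gauss 0.280962 5.000000 0.847918
gauss 0.081430 7.000000 1.445071
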