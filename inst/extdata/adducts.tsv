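# Ion adduct definitions: m/z = (mult * M + delta) / |charge|.
# Proton mass 1.00727646 Da; electron mass neglected in the Na/K/NH4 deltas.
name	delta	charge	mult
[M+H]+	1.00727646	1	1
[M-H]-	-1.00727646	-1	1
[M+Na]+	22.98976928	1	1
[M+K]+	38.96370668	1	1
[M+NH4]+	18.03437413	1	1
[M+H-H2O]+	-17.00328822	1	1
[2M+H]+	1.00727646	1	2
[M+2H]2+	2.01455292	2	1
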