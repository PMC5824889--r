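# Stable-isotope masses (Da) and natural abundances (IUPAC/CODATA values).
# Only elements whose most abundant isotope is also the lightest are listed,
# so the monoisotopic peak is always the first isotopologue group.
# Adduct deltas elsewhere use the proton mass 1.00727646 Da; electron mass is
# neglected for metal/ammonium adduct deltas.
element	mass	abundance
C	12.0	0.9893
C	13.00335483507	0.0107
H	1.00782503207	0.999885
H	2.01410177812	0.000115
N	14.0030740048	0.99636
N	15.0001088982	0.00364
O	15.99491461956	0.99757
O	16.99913170	0.00038
O	17.99916100	0.00205
P	30.97376163	1.0
S	31.97207100	0.9499
S	32.97145876	0.0075
S	33.96786690	0.0425
S	35.96708076	0.0001
Na	22.9897692809	1.0
K	38.96370668	0.932581
K	39.96399848	0.000117
K	40.96182576	0.067302
Cl	34.96885268	0.7576
Cl	36.96590259	0.2424
Br	78.9183371	0.5069
Br	80.9162906	0.4931
F	18.99840322	1.0
I	126.904473	1.0
Si	27.9769265325	0.92223
Si	28.97649470	0.04685
Si	29.97377017	0.03092
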