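# Electron stopping power of liquid water, density 1.0 g/cm3.
# Columns: energy_keV  stopping_keV_per_um
# Points at and above 1 keV follow ICRU/ESTAR collision stopping powers
# (mass stopping power in MeV cm2/g times 0.1 at unit density); points below
# 1 keV are approximate values consistent with published dielectric-model
# track-structure calculations for liquid water.
0.01	4.0
0.02	8.0
0.03	11.0
0.05	15.0
0.10	21.0
0.15	24.0
0.20	25.0
0.30	23.5
0.50	19.5
0.70	16.3
1.0	12.63
1.5	9.57
2.0	7.80
3.0	5.74
4.0	4.63
5.0	3.92
6.0	3.43
8.0	2.77
10.0	2.29
15.0	1.67
20.0	1.32
30.0	0.965
40.0	0.778
50.0	0.660
60.0	0.581
80.0	0.477
100.0	0.412
120.0	0.366
150.0	0.325
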