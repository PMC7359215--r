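# Tc-99m-like synthetic electron spectrum fixture (NOT ICRP-107 data).
# Documented approximate mix: grouped sub-keV Auger lines, conversion
# electrons of the highly converted 2.17 keV transition, K Auger electrons,
# and the 119.5-140 keV conversion-electron lines.
# energy_keV	yield_per_decay
0.03	1.2
0.12	1.0
0.25	0.8
0.45	0.9
1.8	0.55
2.05	0.30
15.4	0.021
119.5	0.088
121.6	0.0066
137.5	0.011
140.0	0.003
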