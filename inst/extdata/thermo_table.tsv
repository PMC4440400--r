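species	dGf0_kJ_per_mol
H2S	-27.87
S0	0.0
SO4	-744.63
S2O3	-523.1
O2	16.4
H2O	-237.17
H+	-39.87
CO2	-386.02
CH2O	-152.87
NO3	-111.34
N2	18.2
NH4	-79.37
NAD+	0.0
NADH	60.99
FAD	0.0
FADH2	42.65
Fd_ox	0.0
Fd_red	38.88
ATP	41.0
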