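# Reference vibrational levels and averaged O-H bond lengths for the
# Glu46-pCA hydrogen bond of photoactive yellow protein at the neutron
# crystal geometry, O...O 2.56 A. Published values, printed to 2
# decimals; bond length at the energy minimum: 1.06 A.
# r_min_angstrom=1.06
isotope	state	energy_kcal_per_mol	mean_R_angstrom
H	0	2.08	1.23
H	1	3.76	1.34
H	2	7.36	1.29
D	0	1.67	1.17
D	1	2.63	1.39
D	2	4.77	1.28
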