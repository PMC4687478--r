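# Reference vibrational levels and averaged O-H bond lengths for the
# Glu46-pCA hydrogen bond of photoactive yellow protein at the
# optimized (equilibrium) geometry, O...O 2.47 A. Published values,
# printed to 2 decimals; bond length at the energy minimum: 1.08 A.
# r_min_angstrom=1.08
isotope	state	energy_kcal_per_mol	mean_R_angstrom
H	0	2.02	1.17
H	1	5.46	1.23
H	2	10.14	1.21
D	0	1.47	1.15
D	1	3.73	1.24
D	2	6.52	1.22
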