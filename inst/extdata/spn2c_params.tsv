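# Three-site-per-nucleotide DNA model constants.  Representative values in
# the published model's ranges; schema documented so the published
# sequence-dependent tables can be substituted.
key	value
bond_k2	0.6
bond_k4	60
angle_k	50
dihedral_gauss_eps	1.67
dihedral_gauss_sigma	0.3
dihedral_periodic_k	0.478
stack_eps	3.6
stack_alpha	3.0
stack_gamma	0.3
bp_eps_AT	4.00
bp_eps_GC	5.37
bp_alpha	2.0
bp_gamma	0.3
cstk_eps	0.8
cstk_alpha	4.0
cstk_gamma	0.25
phosphate_charge	-1
mass_P	94.97
mass_S	83.11
mass_A	134.12
mass_C	110.09
mass_G	150.12
mass_T	125.11
radius_P	2.25
radius_S	3.10
radius_B	2.70
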