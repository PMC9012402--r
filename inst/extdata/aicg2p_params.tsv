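# Structure-based protein model defaults (uniform fallbacks; the published
# sequence-dependent contact and local-term calibrations are external
# parameter data and can be supplied per record instead).
key	value
bond_k	110.4
gauss13_eps	1.0
gauss13_w	1.0
dihedral_gauss_eps	0.45
dihedral_gauss_sigma	0.5
contact_eps	0.3
contact_cutoff	6.5
exv_eps	0.6
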