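property	variant	value	sd
quantum_yield	WT	0.17	NA
quantum_yield	F37S	0.30	0.01
quantum_yield	F37T	0.24	0.01
holo_fraction	WT	0.33	0.01
holo_fraction	F37S	0.49	0.01
holo_fraction	F37T	0.45	0.03
oligomeric_state	WT	1.81	NA
oligomeric_state	F37S	1.78	NA
oligomeric_state	F37T	1.87	NA
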