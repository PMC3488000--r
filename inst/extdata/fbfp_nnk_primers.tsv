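name	target_codon_index_1based	scheme	upstream_flank	downstream_flank
FbFP_F37Xmut	37	NNK	CGTCAACCCGGCC	GAGCGCCTGACC
FbFP_D52Xmut	52	NNK	CGATATTCTCTATCAG	GCACGTTTTCTTCAGG
FbFP_A53Xmut	53	NNK	GACGATATTCTCTATCAGGAC	CGTTTTCTTCAGGGCGAGGAT
FbFP_R54Xmut	54	NNK	TTCTCTATCAGGACGCA	TTTCTTCAGGGCGAGG
FbFP_Q57Xmut	57	NNK	TCTATCAGGACGCACGTTTTCTT	GGCGAGGATCA
FbFP_R70Xmut	70	NNK	GGGCATCGCAATTATC	GAGGCGATCCG
FbFP_N85Xmut	85	NNK	GCCAGGTGCTGCGC	TACCGCAAAGACG
FbFP_W94Xmut	94	NNK	AGACGGCAGCCTGTTC	AACGAGTTGTCCATC
FbFP_Y112Xmut	112	NNK	GACCAGCTGACCTAC	ATCGGCATCCAGCG
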