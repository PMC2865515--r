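site_type	context	dU	PA	GPB	source
NTER_amine	folded	918	900	854	reconstructed
CTER_carboxyl	folded	1460	1435	1394	reconstructed
ARG_side	folded	1080	1026	1026	free_amino_acid
LYS_side	folded	1024	985	978	free_amino_acid
HIS_side	folded	1013	983	971	free_amino_acid
GLN_side	folded	948	919	919	free_amino_acid
ASP_side	folded	1365	1330	1328	free_amino_acid
GLU_side	folded	1368	1358	1356	free_amino_acid
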