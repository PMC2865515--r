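site_type	context	dU	PA	GPB
LYS_side	folded	1024	985	978
LYS_side	linear	961	931	925
ARG_side	folded	1080	1026	1026
ARG_side	linear	1046	1008	1015
HIS_side	folded	1013	983	971
HIS_side	linear	985	953	951
GLN_side	folded	948	919	919
GLN_side	linear	913	877	872
ASP_side	folded	1365	1330	1328
ASP_side	linear	1426	1389	1388
GLU_side	folded	1368	1358	1356
GLU_side	linear	1453	1412	1420
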