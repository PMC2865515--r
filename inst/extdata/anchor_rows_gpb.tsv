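peptide	pattern	pair	dGPB
BK	0 + 0 -	ARG_side/CTER_carboxyl	368
BK	+ 0 0 -	NTER_amine/CTER_carboxyl	540
AN	0 ASH + HID -	ARG_side/CTER_carboxyl	368
AN	0 ASH 0 HIP -	HIS_side/CTER_carboxyl	423
AN	0 - 0 HIP 0	HIS_side/ASP_side	357
AN	0 - + HID 0	ARG_side/ASP_side	302
AN	+ ASH 0 HID -	NTER_amine/CTER_carboxyl	540
TC	0 0 0 ASH + -	ARG_side/CTER_carboxyl	368
TC	0 0 + - 0 0	LYS_side/ASP_side	350
TC	0 0 + ASH 0 -	LYS_side/CTER_carboxyl	416
TC	0 0 0 - + 0	ARG_side/ASP_side	302
TC	+ 0 0 ASH 0 -	NTER_amine/CTER_carboxyl	540
TC	+ 0 0 - 0 0	NTER_amine/ASP_side	474
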