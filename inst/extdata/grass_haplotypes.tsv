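accession_id	marker_id	length_bp	class_letter
AGC_CRI	ITS	697	A
AGC_CRI	matK	395	A
AGC_CRI	rbcL	572	A
AGC_CRI	trnL-F	463	A
BRI	ITS	696	B
BRI	matK	408	B
BRI	rbcL	572	B
BRI	trnL-F	473	B
ELD	ITS	699	C
ELD	matK	408	C
ELD	rbcL	572	C
ELD	trnL-F	473	C
ELS	ITS	701	D
ELS	matK	408	D
ELS	rbcL	572	D
ELS	trnL-F	470	C
ETR	ITS	699	E
ETR	matK	408	E
ETR	rbcL	572	D
ETR	trnL-F	470	D
FER	ITS	695	F
FER	matK	408	F
FER	rbcL	572	E
FER	trnL-F	444	E
LEC	ITS	697	G
LEC	matK	408	G
LEC	rbcL	572	F
LEC	trnL-F	455	F
LOP_MED	ITS	696	H
LOP_MED	matK	408	H
LOP_MED	rbcL	572	G
LOP_MED	trnL-F	453	G
AGC_PEC	ITS	697	I
AGC_PEC	matK	395	I
AGC_PEC	rbcL	572	A
AGC_PEC	trnL-F	458	H
AGM	ITS	682	J
AGM	matK	408	J
AGM	rbcL	572	A
AGM	trnL-F	463	A
AGD	ITS	696	K
AGD	matK	404	K
AGD	rbcL	572	A
AGD	trnL-F	463	H
LOP_PIC	ITS	696	H
LOP_PIC	matK	408	H
LOP_PIC	rbcL	572	G
LOP_PIC	trnL-F	453	G
LOP_TAY	ITS	696	H
LOP_TAY	matK	408	H
LOP_TAY	rbcL	572	G
LOP_TAY	trnL-F	453	G
LOP_ASC	ITS	696	H
LOP_ASC	matK	408	H
LOP_ASC	rbcL	572	G
LOP_ASC	trnL-F	453	G
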