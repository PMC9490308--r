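accession_id	genus	species	infrataxon	infrataxon_rank
AGC_CRI	Agropyron	cristatum	cristatum	variety
BRI	Bromus	inermis		none
ELD	Elymus	dahuricus		none
ELS	Elymus	sibiricus		none
ETR	Elytrigia	repens		none
FER	Festuca	rubra		none
LEC	Leymus	chinensis		none
LOP_MED	Lolium	perenne	Medalist Gold	cultivar
AGC_PEC	Agropyron	cristatum	pectiniforme	variety
AGM	Agropyron	mongolicum		none
AGD	Agropyron	desertorum		none
LOP_PIC	Lolium	perenne	Pickwick	cultivar
LOP_TAY	Lolium	perenne	Taya	cultivar
LOP_ASC	Lolium	perenne	Ascend	cultivar
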