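family	motif_id	consensus
WRKY	wbox	TTGACY
ERF	gccbox	GCCGCC
MYB	myb_core	CNGTTR
TBP	tata_box	TATAWAW
TCP	tcp_site	GGNCCC
SBP	sbp_core	CGTACR
bZIP	gbox	CACGTG
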