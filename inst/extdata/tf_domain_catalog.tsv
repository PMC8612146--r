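domain_id	family	source_db
Pfam_WhiB	WhiB	Pfam
Pfam_Lsr2	Lsr2	Pfam
Pfam_MerR	MerR	Pfam
Pfam_Cro_CI	Cro_CI	Pfam
Pfam_HTH_3	HTH_3	Pfam
Pfam_GntR	GntR	Pfam
Pfam_TetR	TetR	Pfam
Pfam_ArsR	ArsR	Pfam
Pfam_PadR	PadR	Pfam
Pfam_Xre	Xre	Pfam
Pfam_WhiA	WhiA	Pfam
Pfam_RpiR	RpiR	Pfam
Pfam_LuxR	LuxR	Pfam
COG_WhiB	WhiB	COG
COG_Lsr2	Lsr2	COG
COG_MerR	MerR	COG
COG_Cro_CI	Cro_CI	COG
COG_HTH_3	HTH_3	COG
COG_GntR	GntR	COG
COG_TetR	TetR	COG
COG_ArsR	ArsR	COG
COG_PadR	PadR	COG
COG_Xre	Xre	COG
COG_WhiA	WhiA	COG
COG_RpiR	RpiR	COG
COG_LuxR	LuxR	COG
Smart_WhiB	WhiB	Smart
Smart_Lsr2	Lsr2	Smart
Smart_MerR	MerR	Smart
Smart_Cro_CI	Cro_CI	Smart
Smart_HTH_3	HTH_3	Smart
Smart_GntR	GntR	Smart
Smart_TetR	TetR	Smart
Smart_ArsR	ArsR	Smart
Smart_PadR	PadR	Smart
Smart_Xre	Xre	Smart
Smart_WhiA	WhiA	Smart
Smart_RpiR	RpiR	Smart
Smart_LuxR	LuxR	Smart
TIGR_WhiB	WhiB	TIGR
TIGR_Lsr2	Lsr2	TIGR
TIGR_MerR	MerR	TIGR
TIGR_Cro_CI	Cro_CI	TIGR
TIGR_HTH_3	HTH_3	TIGR
TIGR_GntR	GntR	TIGR
TIGR_TetR	TetR	TIGR
TIGR_ArsR	ArsR	TIGR
TIGR_PadR	PadR	TIGR
TIGR_Xre	Xre	TIGR
TIGR_WhiA	WhiA	TIGR
TIGR_RpiR	RpiR	TIGR
TIGR_LuxR	LuxR	TIGR
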