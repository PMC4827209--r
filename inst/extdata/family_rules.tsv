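label	family	subfamily	required	min_copies	forbidden	priority	relax	motif
ABI3/VP1	B3	ABI3/VP1	PF02362			55	0	
AP2	AP2/ERF	AP2	PF00847	2		95	0	
ERF	AP2/ERF	ERF	PF00847	1		40	0	
bHLH	bHLH		PF00010			70	0	
bZIP	bZIP		PF00170,PF07716			69	0	
C2C2-CO-like	C2C2	CO-like	PF00643&PF06203	1&1		96	0	
C2C2-Dof	C2C2	Dof	PF02701			68	0	
C2C2-GATA	C2C2	GATA	PF00320			67	0	
C2C2-LSD	C2C2	LSD	PF06943			66	0	
C2H2	C2H2		PF00096			35	0	
C3H	C3H		PF00642			65	0	
CCAAT	CCAAT		PF00808		CUST_NFYB,CUST_NFYC	38	0	
CPP	CPP		PF03638			64	0	
CSD	CSD		PF00313			63	0	
DBB	C2C2	DBB	PF00643	2	PF06203	94	0	
E2F/DP	E2F/DP		PF02319			62	0	
Fungal TRF	Fungal TRF		PF00172			61	0	
GARP-G2-like	GARP	G2-like	CUST_G2LIKE		PF00072	60	0	
GARP-ARR-B	GARP	ARR-B	CUST_G2LIKE&PF00072	1&1		97	0	
HB-other	Homeobox	HB-other	PF00046		PF05920	39	0	
TALE	Homeobox	TALE	PF05920			93	0	
HSF	HSF		PF00447			59	0	
LIM	LIM		PF00412			58	0	
M-type	MADS-box	M-type	PF00319			57	0	
mTERF	mTERF		PF02536			56	0	
MYB (3R)	MYB	3R	PF00249	3		89	1	
MYB (2R)	MYB	2R	PF00249	2		88	1	
MYB-rel	MYB	rel	PF00249	1		37	1	
MYB-SHAQKYF	MYB	SHAQKYF	PF00249	1		36	1	SH[AL]QK[YF]
NF-X1	NF-X1		PF01422			54	0	
NF-YA	NF-Y	NF-YA	PF02045		CUST_NFYB,CUST_NFYC	90	0	
NF-YB	NF-Y	NF-YB	CUST_NFYB		CUST_NFYC	92	0	
NF-YC	NF-Y	NF-YC	CUST_NFYC		CUST_NFYB	91	0	
Nin-like	Nin-like		PF04937			53	0	
S1Fa-like	S1Fa-like		PF04689			52	0	
SBP	SBP		PF03110			51	0	
Sigma-70	Sigma-70		PF04542			50	0	
TUB	TUB		PF01167			49	0	
VARL	VARL		CUST_VARL			48	0	
Whirly	Whirly		PF08536			47	0	
WRKY	WRKY		PF03106			46	0	
ARF	ARF		PF06507			45	0	
GRAS	GRAS		PF03514			44	0	
NAC	NAC		PF02365			43	0	
arsR	arsR		PF01022			34	0	
Bac_DNA_binding	Bac_DNA_binding		PF00216			33	0	
BolA	BolA		PF01722			32	0	
Crp	Crp		PF00325			31	0	
FUR	FUR		PF01475			30	0	
GerE	GerE		PF00196			29	0	
GntR	GntR		PF00392			28	0	
LysR	LysR		PF00126			27	0	
SfsA	SfsA		PF03749			26	0	
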