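pathway_id	pathway_name	category	gene_symbol	arr
SIG_DEMO1	Growth receptor demo cascade (synthetic)	signaling	GRB7	1
SIG_DEMO1	Growth receptor demo cascade (synthetic)	signaling	KIN2	1
SIG_DEMO1	Growth receptor demo cascade (synthetic)	signaling	PHOS1	-1
SIG_DEMO1	Growth receptor demo cascade (synthetic)	signaling	ADPT3	0.5
SIG_DEMO2	Apoptosis demo branch (synthetic)	signaling	CASP9	1
SIG_DEMO2	Apoptosis demo branch (synthetic)	signaling	BCLX	-1
SIG_DEMO2	Apoptosis demo branch (synthetic)	signaling	APAF1	1
MET_DEMO1	Polyamine demo pathway (synthetic)	metabolic	ODC1	1
MET_DEMO1	Polyamine demo pathway (synthetic)	metabolic	SRM	1
MET_DEMO1	Polyamine demo pathway (synthetic)	metabolic	SMS	0.5
MET_DEMO2	Carnitine demo pathway (synthetic)	metabolic	TMLHE	1
MET_DEMO2	Carnitine demo pathway (synthetic)	metabolic	BBOX1	1
MET_DEMO2	Carnitine demo pathway (synthetic)	metabolic	ALDH9A1	-0.5
MET_DEMO3	Melanin demo pathway (synthetic)	metabolic	TYR	1
MET_DEMO3	Melanin demo pathway (synthetic)	metabolic	DCT	1
MET_DEMO3	Melanin demo pathway (synthetic)	metabolic	PMEL	0
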