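Pathway	NevusVsSkin	PrimaryVsSkin	MetastaticVsSkin	MetastaticVsPrimary	PrimaryVsNevus
Fas Signaling Pathway (Negative)	DOWN	UP	UP	UP	UP
cAMP Pathway (Glycolysis)	UP	DOWN	DOWN	UP	DOWN
CD40 Pathway (Cell Survival)	UP	UP	UP	UP	UP
AKT Pathway (Protein Synthesis)	UP	DOWN	DOWN	DOWN	DOWN
ATM Pathway (Apoptosis, Senescense)	DOWN	UP	UP	UP	UP
BRCA1 Main Pathway	UP	UP	UP	UP	UP
cAMP Pathway (Endothelial Cell Regulation)	UP	DOWN	DOWN	DOWN	DOWN
cAMP Pathway (Myocardial Contraction)	DOWN	DOWN	DOWN	DOWN	DOWN
cAMP Pathway (Protein Retention)	DOWN	UP	UP	UP	UP
Caspase Cascade (Apoptosis)	UP	DOWN	DOWN	DOWN	DOWN
CD40 Pathway (IKBs Degradation)	UP	UP	UP	UP	UP
DDR pathway Apoptosis	DOWN	UP	UP	UP	UP
Glucocorticoid Receptor Pathway (Cell cycle arrest)	UP	DOWN	DOWN	DOWN	DOWN
HGF Pathway (PKC pathway)	UP	UP	UP	UP	DOWN
HIF1-Alpha Main Pathway	UP	UP	UP	UP	UP
JNK Pathway (Insulin signaling)	UP	DOWN	DOWN	DOWN	DOWN
mTOR Pathway (VEGF pathway)	DOWN	DOWN	UP	UP	DOWN
PAK Pathway (Myosin Activation)	DOWN	DOWN	DOWN	DOWN	DOWN
Ubiquitin Proteasome Pathway (Degraded Protein)	DOWN	UP	UP	UP	UP
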