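Pathway	NevusVsSkin	PrimaryVsSkin	MetastaticVsSkin	MetastaticVsPrimary	PrimaryVsNevus
allopregnanolone biosynthesis	UP	DOWN	DOWN	DOWN	DOWN
citrulline-nitric oxide cycle	UP	DOWN	DOWN	DOWN	DOWN
dTMP de novo biosynthesis mitochondrial	DOWN	UP	UP	UP	UP
L-carnitine biosynthesis	UP	DOWN	DOWN	DOWN	DOWN
5-aminoimidazole ribonucleotide biosynthesis	DOWN	UP	UP	UP	UP
eumelanin biosynthesis	UP	UP	UP	DOWN	DOWN
putrescine biosynthesis II	DOWN	DOWN	UP	UP	UP
pyrimidine deoxyribonucleosides salvage	DOWN	UP	UP	UP	UP
spermine and spermidine degradation I	UP	DOWN	DOWN	DOWN	DOWN
superpathway of tryptophan utilization	UP	DOWN	DOWN	UP	DOWN
tryptophan degradation X mammalian via tryptamine	UP	DOWN	DOWN	DOWN	DOWN
1D-myo-inositol hexakisphosphate biosynthesis V from Ins134P3	UP	UP	DOWN	DOWN	UP
D-mannose degradation	UP	UP	UP	UP	DOWN
fructose 26-bisphosphate synthesis, dephosphorylation	UP	UP	UP	DOWN	DOWN
histamine biosynthesis	UP	DOWN	DOWN	DOWN	DOWN
inosine-5-phosphate biosynthesis	UP	UP	UP	UP	DOWN
melatonin degradation II	UP	DOWN	DOWN	DOWN	DOWN
pyrimidine deoxyribonucleosides degradation	UP	UP	UP	DOWN	UP
resolvin D biosynthesis	UP	UP	UP	DOWN	UP
retinoate biosynthesis I	DOWN	DOWN	DOWN	UP	UP
superpathway of steroid hormone biosynthesis	UP	DOWN	DOWN	DOWN	DOWN
tRNA charging	UP	UP	UP	UP	UP
UDP-N-acetyl-D-galactosamine biosynthesis II	UP	UP	UP	UP	DOWN
valine degradation	DOWN	DOWN	DOWN	UP	DOWN
zymosterol biosynthesis	UP	DOWN	DOWN	DOWN	DOWN
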