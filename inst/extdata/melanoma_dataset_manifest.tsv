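dataset_id	platform	n_skin	n_nevus	n_primary	n_metastatic
GSE7553	GPL570	5	0	14	40
GSE53223	GPL570	6	12	0	0
GSE46517	GPL96	8	9	31	52
GSE39612	GPL570	64	0	0	0
GSE31879	GPL570	4	0	10	0
GSE23376	GPL570	0	0	0	22
GSE19234	GPL570	0	0	0	44
GSE15605	GPL570	16	0	46	12
GSE8401	GPL96	0	0	31	52
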