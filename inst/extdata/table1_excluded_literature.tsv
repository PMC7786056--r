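gene_id	description	trivial_name	id_source
CSA032195	G-type lectin S-receptor-like serine/threonine-protein kinase	GsSRK	table1
CSA031147	G-type lectin S-receptor-like serine/threonine-protein kinase RKS1	GsSRK1	table1
CSA020614	Receptor-like serine/threonine-protein kinase ALE2	RPK2/ALE2	table1
CSA034862	Ethylene response factor 6	AP2/ERF-ERF6	table1
WRKY2	WRKY transcription factor 2	WRKY2	synthetic
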