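source	gene_id	description	trivial_name	id_source
interspecies	TEA003328	Galactinol synthase 1	GOLS1	table1
interspecies	TEA006793	Galactinol synthase 3	GOLS3	table1
interspecies	TEA030611	Glycine-rich RNA-binding protein 3	GR-RBP3	table1
interspecies	TEA021045	Endotransglucosylase	HYDROLASE22	table1
interspecies	TEA020473	Responsive to high light 41	RHL41	table1
interspecies	TEA010353	Calcium underaccumulation 1	CAU1	table1
interspecies	TEA003997	Pectin methylesterase 41	PME41	table1
interspecies	TEA004079	Dehydration response element-binding protein 26	DREB26	table1
interspecies	TEA024722	Aba- and osmotic-stress-inducible protein kinase	ARCK1/CRK45	table1
literature	CSA001565	LRR receptor-like serine/threonine-protein kinase FLS2-like	FLS2	table1
literature	CSA000608	Ethylene-responsive transcription factor ERF021	AP2/ERF-AP21	table1
literature	CSA000348	Ethylene-responsive transcription factor SHINE 2-like	AP2/ERF-ERF2	table1
literature	CSA023474	bHLH transcription factor bHLH102	bHLH102	table1
literature	CSA033910	Probable WRKY transcription factor 42	WRKY42	table1
literature	CSA002423	Zinc finger CCCH domain-containing protein 30	ZAT30	table1
literature	CSA003726	Late embryogenesis abundant protein 3L-1	LEA3	table1
literature	CSA031822	Late embryogenesis abundant protein	LEA2	table1
literature	CSA012537	Heat shock 70 kDa protein, mitochondrial-like	HSP70	table1
literature	CSA014200	36.4 kDa proline-rich protein-like	PRP	table1
literature	CSA016010	Putative cold-inducible protein	CIP	table1
literature	CSA001876	Probable pectinesterase/pectinesterase inhibitor 54	PEI54	table1
literature	CSA035791	Endoglucanase 11-like	EGase11	table1
literature	CSA000129	Thaumatin-like protein 1b	TLP1	table1
literature	CSA028426	Peroxidase 73	POD73	table1
literature	CSA006422	Glutathione S-transferase	GST	table1
literature	CSA010521	Beta-amylase 5	BMY5	table1
literature	CSA000011	Sucrose synthase 1	SUS1	table1
literature	bHLH7	bHLH transcription factor 7	bHLH7	synthetic
literature	bHLH12	bHLH transcription factor 12	bHLH12	synthetic
literature	bHLH21	bHLH transcription factor 21	bHLH21	synthetic
literature	bHLH43	bHLH transcription factor 43	bHLH43	synthetic
literature	bHLH45	bHLH transcription factor 45	bHLH45	synthetic
literature	bHLH79	bHLH transcription factor 79	bHLH79	synthetic
literature	bHLH93	bHLH transcription factor 93	bHLH93	synthetic
literature	bHLH95	bHLH transcription factor 95	bHLH95	synthetic
literature	SnRK1.1	SNF1-related protein kinase 1.1	SnRK1.1	synthetic
literature	SnRK1.2	SNF1-related protein kinase 1.2	SnRK1.2	synthetic
literature	SnRK1.3	SNF1-related protein kinase 1.3	SnRK1.3	synthetic
literature	HXK1	Hexokinase 1	HXK1	synthetic
literature	HXK2	Hexokinase 2	HXK2	synthetic
literature	HXK3	Hexokinase 3	HXK3	synthetic
literature	CBF1	C-repeat binding factor 1	CBF1	synthetic
literature	ICE1	Inducer of CBF expression 1	ICE1	synthetic
literature	DHN1	Dehydrin 1	DHN1	synthetic
literature	DHN3	Dehydrin 3	DHN3	synthetic
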