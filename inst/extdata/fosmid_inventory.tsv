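accession	fosmid	insert_length_bp	n_contigs	target_gene	probe
EU024823	01I13	40701	2	HY5	HY5
EU024826	08G19	38293	1	APETALA 3	AP3
EU024827	10B08	35178	1	LEAFY	LFY
EU024831	13I24	33654	1	NBS-LRR Resistance-like gene	gRGA2
EU024832	14K06	36024	1	ALCOHOL DEHYDROGENASE	ADH
EU024837	19H07	32060	3	SUPPRESSOR OF CONSTANS I	SOC
EU024838	19M24	32776	1	NBS-LRR Resistance-like gene	gRGA1
EU024845	32L07	32968	1	NBS-LRR Resistance-like gene	gRGA2
EU024847	34E24	36278	1	NBS-LRR Resistance-like gene	gRGA1
EU024852	41O22	32997	1	TERPENE SYNTHASE	TPS
EU024856	48I08	38603	3	CHALCONE ISOMERASE	CHI
EU024859	49M15	42209	3	LRR Resistance-like gene	gLRR
EU024860	51F10	29623	1	PHYTOCHROME A	PHY
EU024861	52B01	29916	1	CONSTANS	CO
EU024863	52I20	42439	1	GRANULE-BOUND STARCH SYNTHASE-I	GBSSI
EU024864	53J04	32846	2	TERPENE SYNTHASE	TPS
EU024865	53O08	31107	3	DIHYDROFLAVONOL 4-REDUCTASE	DFR
EU024868	73I22	33392	1	CHALCONE SYNTHASE	CHS
EU024870	76C08	44532	3	REGULATOR OF ANTHOCYANIN SYNTHESIS	RAN
EU024871	76K13	32767	1	PISTILLATA	PIST
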