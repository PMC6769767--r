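gene	drug	gscore	dscore	response	association	drug_status	indications
DDR2	dasatinib	0.64	0.95	sensitivity	direct_target	clinical_trials	nsclc
T016G001	paclitaxel	0.63	0.94	sensitivity	biomarker	approved	nsclc,breast_carcinoma
T016G002	pemetrexed	0.79	0.84	sensitivity	biomarker	approved	nsclc
C8G01	sorafenib	0.6	0.92	sensitivity	direct_target	approved	hcc,rcc
C12G01	axitinib	0.58	0.91	sensitivity	direct_target	approved	rcc
C4G01	cpd-0016x	0.4	0.5	sensitivity	pathway_member	experimental	.
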