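gene	drug	gscore	dscore	response	association	drug_status	indications
ERBB4	vandetanib	0.72	0.92	sensitivity	direct_target	approved	thyroid_carcinoma
FLT4	vandetanib	0.68	0.88	sensitivity	direct_target	approved	thyroid_carcinoma
ETV6	imatinib	0.81	0.86	sensitivity	direct_target	approved	cml,aml
U933G03	acalabrutinib	0.66	0.83	sensitivity	direct_target	approved	cll
U933G04	osimertinib	0.7	0.81	sensitivity	direct_target	approved	nsclc
U933G05	idarubicin	0.75	0.79	sensitivity	biomarker	approved	aml
U933G06	cpd-0933a	0.41	0.55	sensitivity	pathway_member	experimental	.
U933G07	cpd-0933b	0.38	0.48	sensitivity	pathway_member	experimental	.
U933G08	cpd-0933c	0.45	0.42	sensitivity	pathway_member	experimental	.
U933G09	cpd-0933d	0.36	0.35	sensitivity	biomarker	experimental	.
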