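gene	drug	gscore	dscore	response	association	drug_status	indications
T056G001	paclitaxel	0.63	0.9	sensitivity	biomarker	approved	nsclc,breast_carcinoma
T056G002	pemetrexed	0.71	0.85	sensitivity	biomarker	approved	nsclc
T056G003	alectinib	0.66	0.8	sensitivity	pathway_member	approved	nsclc
T056G004	cpd-0056t04	0.3	0.25	sensitivity	pathway_member	experimental	.
T056G005	cpd-0056t05	0.312	0.267	sensitivity	pathway_member	experimental	.
T056G006	cpd-0056t06	0.324	0.283	sensitivity	pathway_member	experimental	.
T056G007	cpd-0056t07	0.336	0.3	sensitivity	pathway_member	experimental	.
T056G008	cpd-0056t08	0.348	0.317	sensitivity	pathway_member	experimental	.
T056G009	cpd-0056t09	0.36	0.333	sensitivity	pathway_member	experimental	.
T056G010	cpd-0056t10	0.371	0.35	sensitivity	pathway_member	experimental	.
T056G011	cpd-0056t11	0.383	0.367	sensitivity	pathway_member	experimental	.
T056G012	cpd-0056t12	0.395	0.383	sensitivity	pathway_member	experimental	.
T056G013	cpd-0056t13	0.407	0.4	sensitivity	pathway_member	experimental	.
T056G014	cpd-0056t14	0.419	0.417	sensitivity	pathway_member	experimental	.
T056G015	cpd-0056t15	0.431	0.433	sensitivity	pathway_member	experimental	.
T056G016	cpd-0056t16	0.443	0.45	sensitivity	pathway_member	experimental	.
T056G017	cpd-0056t17	0.455	0.467	sensitivity	pathway_member	experimental	.
T056G018	cpd-0056t18	0.467	0.483	sensitivity	pathway_member	experimental	.
T056G019	cpd-0056t19	0.479	0.5	sensitivity	pathway_member	experimental	.
T056G020	cpd-0056t20	0.49	0.517	sensitivity	pathway_member	experimental	.
T056G021	cpd-0056t21	0.502	0.533	sensitivity	pathway_member	experimental	.
T056G022	cpd-0056t22	0.514	0.55	sensitivity	pathway_member	experimental	.
T056G023	cpd-0056t23	0.526	0.567	sensitivity	pathway_member	experimental	.
T056G024	cpd-0056t24	0.538	0.583	sensitivity	pathway_member	experimental	.
T056G025	cpd-0056t25	0.55	0.6	sensitivity	pathway_member	experimental	.
TP53	paclitaxel	0.92	0.9	sensitivity	biomarker	approved	nsclc,breast_carcinoma
CAMK4	gemcitabine	0.58	0.78	sensitivity	biomarker	approved	nsclc,pancreatic_carcinoma
S056G01	cpd-0056s01	0.32	0.28	sensitivity	pathway_member	experimental	.
S056G02	cpd-0056s02	0.36	0.34	sensitivity	pathway_member	experimental	.
S056G03	cpd-0056s03	0.4	0.4	sensitivity	pathway_member	experimental	.
S056G04	cpd-0056s04	0.44	0.46	sensitivity	pathway_member	experimental	.
S056G05	cpd-0056s05	0.48	0.52	sensitivity	pathway_member	experimental	.
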