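event_id	category
SH001	shared
SH002	shared
SH003	shared
SH004	shared
SH005	shared
SH006	shared
SH007	shared
SH008	shared
SH009	shared
SH010	shared
SH011	shared
SH012	shared
SH013	shared
SH014	shared
SH015	shared
SH016	shared
SH017	shared
SH018	shared
SH019	shared
SH020	shared
SH021	shared
SH022	shared
SH023	shared
SH024	shared
SH025	shared
SH026	shared
SH027	shared
SH028	shared
SH029	shared
SH030	shared
SH031	shared
SH032	shared
SH033	shared
SH034	shared
SH035	shared
SH036	shared
SH037	shared
SH038	shared
SH039	shared
SH040	shared
SH041	shared
SH042	shared
SH043	shared
SH044	shared
SH045	shared
SH046	shared
SH047	shared
SH048	shared
SH049	shared
SH050	shared
SH051	shared
SH052	shared
SH053	shared
SH054	shared
SH055	shared
SH056	shared
SH057	shared
SH058	shared
SH059	shared
SH060	shared
SH061	shared
SH062	shared
SH063	shared
SH064	shared
SH065	shared
SH066	shared
SH067	shared
SH068	shared
SH069	shared
SH070	shared
SH071	shared
SH072	shared
SH073	shared
SH074	shared
SH075	shared
SH076	shared
SH077	shared
SH078	shared
SH079	shared
SH080	shared
SH081	shared
SH082	shared
SH083	shared
SH084	shared
SH085	shared
SH086	shared
SH087	shared
SH088	shared
SH089	shared
SH090	shared
SH091	shared
SH092	shared
SH093	shared
SH094	shared
SH095	shared
SH096	shared
SH097	shared
SH098	shared
SH099	shared
SH100	shared
SH101	shared
SH102	shared
SH103	shared
SH104	shared
SH105	shared
SH106	shared
SH107	shared
SH108	shared
SH109	shared
SH110	shared
SH111	shared
SH112	shared
SH113	shared
SH114	shared
SH115	shared
SH116	shared
SH117	shared
SH118	shared
SH119	shared
SH120	shared
SH121	shared
SH122	shared
SH123	shared
SH124	shared
SH125	shared
SH126	shared
SH127	shared
SH128	shared
SH129	shared
SH130	shared
SH131	shared
SH132	shared
SH133	shared
SH134	shared
SH135	shared
SH136	shared
SH137	shared
SH138	shared
SH139	shared
SH140	shared
SH141	shared
SH142	shared
SH143	shared
SH144	shared
SH145	shared
SH146	shared
SH147	shared
SH148	shared
SH149	shared
SH150	shared
SH151	shared
SH152	shared
SH153	shared
SH154	shared
SH155	shared
SH156	shared
SH157	shared
SH158	shared
SH159	shared
SH160	shared
SH161	shared
SH162	shared
SH163	shared
SH164	shared
SH165	shared
SH166	shared
SH167	shared
SH168	shared
SH169	shared
SH170	shared
SH171	shared
SH172	shared
SH173	shared
SH174	shared
SH175	shared
SH176	shared
SH177	shared
SH178	shared
SH179	shared
SH180	shared
SH181	shared
SH182	shared
SH183	shared
SH184	shared
SH185	shared
SH186	shared
SH187	shared
SH188	shared
SH189	shared
SH190	shared
SH191	shared
SH192	shared
SH193	shared
SH194	shared
SH195	shared
SH196	shared
SH197	shared
SH198	shared
SH199	shared
SH200	shared
SH201	shared
SH202	shared
SH203	shared
SH204	shared
SH205	shared
SH206	shared
SH207	shared
SH208	shared
SH209	shared
SH210	shared
SH211	shared
SH212	shared
SH213	shared
SH214	shared
SH215	shared
SH216	shared
SH217	shared
SH218	shared
SH219	shared
SH220	shared
SH221	shared
SH222	shared
SH223	shared
SH224	shared
SH225	shared
SH226	shared
SH227	shared
SH228	shared
SH229	shared
SH230	shared
SH231	shared
SH232	shared
SH233	shared
SH234	shared
SH235	shared
SH236	shared
SH237	shared
SH238	shared
SH239	shared
SH240	shared
SH241	shared
SH242	shared
SH243	shared
SH244	shared
SH245	shared
SH246	shared
SH247	shared
SH248	shared
SH249	shared
SH250	shared
SH251	shared
SH252	shared
SH253	shared
SH254	shared
SH255	shared
SH256	shared
SH257	shared
SH258	shared
SH259	shared
SH260	shared
SH261	shared
SH262	shared
SH263	shared
SH264	shared
SH265	shared
SH266	shared
SH267	shared
SH268	shared
SH269	shared
SH270	shared
SH271	shared
SH272	shared
SH273	shared
SH274	shared
SH275	shared
SH276	shared
SH277	shared
SH278	shared
SH279	shared
SH280	shared
SH281	shared
SH282	shared
SH283	shared
SH284	shared
SH285	shared
SH286	shared
SH287	shared
SH288	shared
SH289	shared
SH290	shared
SH291	shared
SH292	shared
SH293	shared
SH294	shared
SH295	shared
SH296	shared
SH297	shared
SH298	shared
SH299	shared
SH300	shared
SH301	shared
SH302	shared
SH303	shared
SH304	shared
SH305	shared
SH306	shared
SH307	shared
SH308	shared
SH309	shared
SH310	shared
SH311	shared
SH312	shared
SH313	shared
SH314	shared
SH315	shared
SH316	shared
SH317	shared
SH318	shared
SH319	shared
SH320	shared
SH321	shared
SH322	shared
SH323	shared
SH324	shared
SH325	shared
SH326	shared
SH327	shared
SH328	shared
SH329	shared
SH330	shared
PR001	primary_specific
PR002	primary_specific
PR003	primary_specific
PR004	primary_specific
PR005	primary_specific
RL001	relapse_specific
RL002	relapse_specific
RL003	relapse_specific
RL004	relapse_specific
RL005	relapse_specific
RL006	relapse_specific
RL007	relapse_specific
RL008	relapse_specific
RL009	relapse_specific
RL010	relapse_specific
RL011	relapse_specific
RL012	relapse_specific
RL013	relapse_specific
RL014	relapse_specific
RL015	relapse_specific
RL016	relapse_specific
RL017	relapse_specific
RL018	relapse_specific
RL019	relapse_specific
RL020	relapse_specific
RL021	relapse_specific
RL022	relapse_specific
RL023	relapse_specific
RL024	relapse_specific
RL025	relapse_specific
RL026	relapse_specific
RL027	relapse_specific
RL028	relapse_specific
RL029	relapse_specific
RL030	relapse_specific
RL031	relapse_specific
RL032	relapse_specific
RL033	relapse_specific
RL034	relapse_specific
RL035	relapse_specific
RL036	relapse_specific
RL037	relapse_specific
RL038	relapse_specific
RL039	relapse_specific
RL040	relapse_specific
RL041	relapse_specific
RL042	relapse_specific
RL043	relapse_specific
RL044	relapse_specific
RL045	relapse_specific
RL046	relapse_specific
RL047	relapse_specific
RL048	relapse_specific
RL049	relapse_specific
RL050	relapse_specific
RL051	relapse_specific
RL052	relapse_specific
RL053	relapse_specific
RL054	relapse_specific
RL055	relapse_specific
RL056	relapse_specific
RL057	relapse_specific
RL058	relapse_specific
RL059	relapse_specific
RL060	relapse_specific
RL061	relapse_specific
RL062	relapse_specific
RL063	relapse_specific
RL064	relapse_specific
RL065	relapse_specific
RL066	relapse_specific
RL067	relapse_specific
RL068	relapse_specific
RL069	relapse_specific
RL070	relapse_specific
RL071	relapse_specific
RL072	relapse_specific
RL073	relapse_specific
RL074	relapse_specific
RL075	relapse_specific
RL076	relapse_specific
RL077	relapse_specific
RL078	relapse_specific
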