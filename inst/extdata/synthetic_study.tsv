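metabolite	time_min	comparison	fold_change	sd	source	role
2PG	3	high_vs_low	0.942249704140679	0.0721133613921566	spegel2013	train
3PG	3	high_vs_low	1.06153446078414	0.17934918292209	spegel2013	train
AKG	3	high_vs_low	1.09646041118152	0.0195500138629634	spegel2013	train
ALA	3	high_vs_low	1.10242895513561	0.143009548985508	spegel2013	train
ASP	3	high_vs_low	0.939656109562529	0.219027077131917	spegel2013	train
CIT	3	high_vs_low	1.07485620809855	0.0863608423641906	spegel2013	train
FUM	3	high_vs_low	1.14163405056007	0.026497429625549	spegel2013	train
G3P	3	high_vs_low	1.15849565106335	0.221983375747169	spegel2013	train
LAC	3	high_vs_low	1.02546636176595	0.0614096613427009	spegel2013	train
MAL	3	high_vs_low	0.951690697684537	0.124968714343012	spegel2013	train
PEP	3	high_vs_low	1.08084386674292	0.113981229657291	spegel2013	train
PYR	3	high_vs_low	1.05919710301538	0.0991844127562372	spegel2013	train
R5P	3	high_vs_low	1.03052018822447	0.115571273054108	spegel2013	train
SUC	3	high_vs_low	1.0426817235532	0.0837690318428242	spegel2013	train
2PG	6	high_vs_low	1.01681260989289	0.105004066010109	spegel2013	validation
3PG	6	high_vs_low	1.01242727410472	0.105464166802814	spegel2013	validation
AKG	6	high_vs_low	1.17084253700948	0.081167601190552	spegel2013	validation
ALA	6	high_vs_low	1.04337275039362	0.110200551890608	spegel2013	validation
ASP	6	high_vs_low	1.15741828915871	0.190215948306259	spegel2013	validation
CIT	6	high_vs_low	1.19981423061552	0.134497392256341	spegel2013	validation
FUM	6	high_vs_low	1.46048848852876	0.262725867995516	spegel2013	validation
G3P	6	high_vs_low	1.80775074648735	0.123554231825593	spegel2013	validation
LAC	6	high_vs_low	1.05049297588556	0.234765509628933	spegel2013	validation
MAL	6	high_vs_low	1.31317194985607	0.269112306835823	spegel2013	validation
PEP	6	high_vs_low	0.920807205397291	0.132453723571426	spegel2013	validation
PYR	6	high_vs_low	1.65417119555895	0.0850712961321944	spegel2013	validation
R5P	6	high_vs_low	0.941601935323735	0.0503964252753309	spegel2013	validation
SUC	6	high_vs_low	1.24001568090534	0.232495549111547	spegel2013	validation
2PG	10	high_vs_low	1.01126404042125	0.0526403207165598	spegel2013	train
3PG	10	high_vs_low	0.942034770051212	0.0471628206572995	spegel2013	train
AKG	10	high_vs_low	1.76099461089425	0.234861870292163	spegel2013	train
ALA	10	high_vs_low	1.59307996091369	0.126550891764122	spegel2013	train
ASP	10	high_vs_low	0.846765973367697	0.0470775033070592	spegel2013	train
CIT	10	high_vs_low	1.93746288702528	0.0952347263564449	spegel2013	train
FUM	10	high_vs_low	2.16304316916126	0.171469212810096	spegel2013	train
G3P	10	high_vs_low	4.45665770659214	0.354730593268659	spegel2013	train
LAC	10	high_vs_low	1.30693433899505	0.213519877998613	spegel2013	train
MAL	10	high_vs_low	2.04741622799933	0.342920480667709	spegel2013	train
PEP	10	high_vs_low	0.876140254112205	0.0114550354967184	spegel2013	train
PYR	10	high_vs_low	3.46185531769846	0.206399116101068	spegel2013	train
R5P	10	high_vs_low	1.03573959837323	0.148644371728542	spegel2013	train
SUC	10	high_vs_low	2.34462278147263	0.16481419726714	spegel2013	train
2PG	15	high_vs_low	0.609367621835112	0.0303643123628989	spegel2013	validation
3PG	15	high_vs_low	0.616574276123937	0.0282323724236745	spegel2013	validation
AKG	15	high_vs_low	3.18739725684142	0.477327275004153	spegel2013	validation
ALA	15	high_vs_low	2.15011723102152	0.192814783753556	spegel2013	validation
ASP	15	high_vs_low	0.794412834806878	0.10275126104018	spegel2013	validation
CIT	15	high_vs_low	4.64727370726486	0.935592552946897	spegel2013	validation
FUM	15	high_vs_low	6.29741076695724	1.62959903002318	spegel2013	validation
G3P	15	high_vs_low	7.84642302507618	0.982738864031318	spegel2013	validation
LAC	15	high_vs_low	1.92666466330835	0.104831770047428	spegel2013	validation
MAL	15	high_vs_low	4.2182067804134	0.169167624050329	spegel2013	validation
PEP	15	high_vs_low	0.598797927671946	0.104349745745969	spegel2013	validation
PYR	15	high_vs_low	9.99187471235673	1.53861782803882	spegel2013	validation
R5P	15	high_vs_low	1.10029455722788	0.136506222973056	spegel2013	validation
SUC	15	high_vs_low	6.33095962865186	1.69263887914138	spegel2013	validation
AKG	60	high_vs_low	5.68672224692607	1.09931994043067	malmgren	train
ALA	60	high_vs_low	9.61222334017668	0.366659587119495	malmgren	train
ASP	60	high_vs_low	0.903511996034108	0.0744862996922722	malmgren	train
CIT	60	high_vs_low	8.79856282452392	0.70193311923413	malmgren	train
FUM	60	high_vs_low	9.60877861761285	1.47167552415268	malmgren	train
G3P	60	high_vs_low	9.2217104673998	1.27180141244409	malmgren	train
G6P	60	high_vs_low	14.2502874884268	2.48944720030271	malmgren	train
GLC	60	high_vs_low	3.27087476455448	0.302276854179423	malmgren	train
GLU	60	high_vs_low	1.01072929616452	0.155138604293423	malmgren	train
ICIT	60	high_vs_low	4.82174630487919	1.01041243718523	malmgren	train
LAC	60	high_vs_low	2.45308085811137	0.15373277651307	malmgren	train
MAL	60	high_vs_low	10.9046105531373	1.64867944712462	malmgren	train
PYR	60	high_vs_low	5.32084120216474	1.70305001844685	malmgren	train
SUC	60	high_vs_low	9.88204194206768	0.424949035934976	malmgren	train
2PG	6	vs_t0	0.981290494316351	0.0585912942881054	spegel2015	train
3PG	6	vs_t0	1.05820802591545	0.21384861857083	spegel2015	train
AKG	6	vs_t0	1.06688977025039	0.141044620415631	spegel2015	train
ALA	6	vs_t0	1.02787658532241	0.135972355946214	spegel2015	train
CIT	6	vs_t0	1.11438122434731	0.0638596877949918	spegel2015	train
F6P	6	vs_t0	1.97943095082224	0.486417588329253	spegel2015	train
FUM	6	vs_t0	1.22733183729993	0.116997054562179	spegel2015	train
G6P	6	vs_t0	1.74146599291581	0.409326595225356	spegel2015	train
ICIT	6	vs_t0	1.36204231100903	0.0714151770194218	spegel2015	train
LAC	6	vs_t0	1.04566989995648	0.165890265536685	spegel2015	train
MAL	6	vs_t0	1.298213638116	0.0735691280438169	spegel2015	train
PEP	6	vs_t0	0.924435304899841	0.212088488553981	spegel2015	train
R5P	6	vs_t0	0.946113993503639	0.0260044194464238	spegel2015	train
SUC	6	vs_t0	1.34971030996693	0.0863666424963713	spegel2015	train
2PG	15	vs_t0	0.644058138242695	0.0458587784279121	spegel2015	train
3PG	15	vs_t0	0.63509820863981	0.155893868677318	spegel2015	train
AKG	15	vs_t0	3.41427918262357	0.326882800862573	spegel2015	train
ALA	15	vs_t0	2.42224652748291	0.240063135758474	spegel2015	train
CIT	15	vs_t0	5.19766431709647	0.811118276031413	spegel2015	train
F6P	15	vs_t0	3.67462807848931	0.229208572047937	spegel2015	train
FUM	15	vs_t0	5.91932140185342	0.5162981439377	spegel2015	train
G6P	15	vs_t0	5.02720001062183	0.895488386391616	spegel2015	train
ICIT	15	vs_t0	5.01266424393812	1.1148906676292	spegel2015	train
LAC	15	vs_t0	2.00335665821593	0.185207783409407	spegel2015	train
MAL	15	vs_t0	5.0136644060436	0.828500223272023	spegel2015	train
PEP	15	vs_t0	0.60513332666498	0.0909936706912846	spegel2015	train
R5P	15	vs_t0	1.08377690942374	0.105195705381862	spegel2015	train
SUC	15	vs_t0	5.85273649868904	0.786812607736142	spegel2015	train
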