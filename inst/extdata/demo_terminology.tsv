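term	terminology	concept_id	preferred_term
Voraufnahmen	SNOMED-CT	SCT-001258	Voraufnahmen
Voraufnahmen	Wingert	WGT-08806	VORAUFNAHMEN
2015	SNOMED-CT	SCT-000200	2015
2015	Wingert	WGT-01400	2015
2017	SNOMED-CT	SCT-000202	2017
2017	Wingert	WGT-01414	2017
2019	SNOMED-CT	SCT-000204	2019
2019	Wingert	WGT-01428	2019
2021	SNOMED-CT	SCT-000197	2021
2021	Wingert	WGT-01379	2021
Keine	SNOMED-CT	SCT-000492	Keine
Keine	Wingert	WGT-03444	KEINE
Haut und Subkutis	SNOMED-CT	SCT-001651	Haut und Subkutis
Haut und Subkutis	Wingert	WGT-11557	HAUT UND SUBKUTIS
Kutis und Subkutis	SNOMED-CT	SCT-001777	Kutis und Subkutis
Kutis und Subkutis	Wingert	WGT-12439	KUTIS UND SUBKUTIS
unauffällig	SNOMED-CT	SCT-001297	unauffällig
unauffällig	Wingert	WGT-09079	UNAUFFÄLLIG
verdickt	SNOMED-CT	SCT-000860	verdickt
verdickt	Wingert	WGT-06020	VERDICKT
beidseits	SNOMED-CT	SCT-000956	beidseits
beidseits	Wingert	WGT-06692	BEIDSEITS
links	SNOMED-CT	SCT-000545	links
links	Wingert	WGT-03815	LINKS
rechts	SNOMED-CT	SCT-000649	rechts
rechts	Wingert	WGT-04543	RECHTS
Mamillenregion	SNOMED-CT	SCT-001459	Mamillenregion
Mamillenregion	Wingert	WGT-10213	MAMILLENREGION
Mamille	SNOMED-CT	SCT-000705	Mamille
Mamille	Wingert	WGT-04935	MAMILLE
eingezogen	SNOMED-CT	SCT-001067	eingezogen
eingezogen	Wingert	WGT-07469	EINGEZOGEN
linken	SNOMED-CT	SCT-000641	linken
linken	Wingert	WGT-04487	LINKEN
rechten	SNOMED-CT	SCT-000745	rechten
rechten	Wingert	WGT-05215	RECHTEN
rundliche	SNOMED-CT	SCT-000958	rundliche
rundliche	Wingert	WGT-06706	RUNDLICHE
ovale	SNOMED-CT	SCT-000535	ovale
ovale	Wingert	WGT-03745	OVALE
irreguläre	SNOMED-CT	SCT-001205	irreguläre
irreguläre	Wingert	WGT-08435	IRREGULÄRE
lobulierte	SNOMED-CT	SCT-001079	lobulierte
lobulierte	Wingert	WGT-07553	LOBULIERTE
Läsion	SNOMED-CT	SCT-000745	Läsion
Läsion	Wingert	WGT-05215	LÄSION
Verdichtung	SNOMED-CT	SCT-001155	Verdichtung
Verdichtung	Wingert	WGT-08085	VERDICHTUNG
Raumforderung	SNOMED-CT	SCT-001377	Raumforderung
Raumforderung	Wingert	WGT-09639	RAUMFORDERUNG
oberen äußeren	SNOMED-CT	SCT-001661	oberen äußeren
oberen äußeren	Wingert	WGT-11627	OBEREN ÄUßEREN
oberen inneren	SNOMED-CT	SCT-001418	oberen inneren
oberen inneren	Wingert	WGT-09926	OBEREN INNEREN
unteren äußeren	SNOMED-CT	SCT-001795	unteren äußeren
unteren äußeren	Wingert	WGT-12565	UNTEREN ÄUßEREN
unteren inneren	SNOMED-CT	SCT-001552	unteren inneren
unteren inneren	Wingert	WGT-10864	UNTEREN INNEREN
1 Uhr	SNOMED-CT	SCT-000384	1 Uhr
1 Uhr	Wingert	WGT-02688	1 UHR
2 Uhr	SNOMED-CT	SCT-000385	2 Uhr
2 Uhr	Wingert	WGT-02695	2 UHR
3 Uhr	SNOMED-CT	SCT-000386	3 Uhr
3 Uhr	Wingert	WGT-02702	3 UHR
4 Uhr	SNOMED-CT	SCT-000387	4 Uhr
4 Uhr	Wingert	WGT-02709	4 UHR
5 Uhr	SNOMED-CT	SCT-000388	5 Uhr
5 Uhr	Wingert	WGT-02716	5 UHR
6 Uhr	SNOMED-CT	SCT-000389	6 Uhr
6 Uhr	Wingert	WGT-02723	6 UHR
7 Uhr	SNOMED-CT	SCT-000390	7 Uhr
7 Uhr	Wingert	WGT-02730	7 UHR
8 Uhr	SNOMED-CT	SCT-000391	8 Uhr
8 Uhr	Wingert	WGT-02737	8 UHR
9 Uhr	SNOMED-CT	SCT-000392	9 Uhr
9 Uhr	Wingert	WGT-02744	9 UHR
10 Uhr	SNOMED-CT	SCT-000432	10 Uhr
10 Uhr	Wingert	WGT-03024	10 UHR
11 Uhr	SNOMED-CT	SCT-000433	11 Uhr
11 Uhr	Wingert	WGT-03031	11 UHR
12 Uhr	SNOMED-CT	SCT-000434	12 Uhr
12 Uhr	Wingert	WGT-03038	12 UHR
Keinerlei	SNOMED-CT	SCT-000920	Keinerlei
Keinerlei	Wingert	WGT-06440	KEINERLEI
Herdbefunde	SNOMED-CT	SCT-001116	Herdbefunde
Herdbefunde	Wingert	WGT-07812	HERDBEFUNDE
Mamillenabstand	SNOMED-CT	SCT-001548	Mamillenabstand
Mamillenabstand	Wingert	WGT-10836	MAMILLENABSTAND
Gruppierte	SNOMED-CT	SCT-001063	Gruppierte
Gruppierte	Wingert	WGT-07441	GRUPPIERTE
Vereinzelte	SNOMED-CT	SCT-001165	Vereinzelte
Vereinzelte	Wingert	WGT-08155	VEREINZELTE
Polymorphe	SNOMED-CT	SCT-001071	Polymorphe
Polymorphe	Wingert	WGT-07497	POLYMORPHE
Verkalkungen	SNOMED-CT	SCT-001261	Verkalkungen
Verkalkungen	Wingert	WGT-08827	VERKALKUNGEN
Mikroverkalkungen	SNOMED-CT	SCT-001807	Mikroverkalkungen
Mikroverkalkungen	Wingert	WGT-12649	MIKROVERKALKUNGEN
Mikro- oder Makroverkalkungen	SNOMED-CT	SCT-002848	Mikro- oder Makroverkalkungen
Mikro- oder Makroverkalkungen	Wingert	WGT-19936	MIKRO- ODER MAKROVERKALKUNGEN
Asymmetrie	SNOMED-CT	SCT-001056	Asymmetrie
Asymmetrie	Wingert	WGT-07392	ASYMMETRIE
Parenchymasymmetrie	SNOMED-CT	SCT-002023	Parenchymasymmetrie
Parenchymasymmetrie	Wingert	WGT-14161	PARENCHYMASYMMETRIE
Architekturstörung	SNOMED-CT	SCT-002079	Architekturstörung
Architekturstörung	Wingert	WGT-14553	ARCHITEKTURSTÖRUNG
Clipmarkierung	SNOMED-CT	SCT-001469	Clipmarkierung
Clipmarkierung	Wingert	WGT-10283	CLIPMARKIERUNG
Silikonimplantat	SNOMED-CT	SCT-001699	Silikonimplantat
Silikonimplantat	Wingert	WGT-11893	SILIKONIMPLANTAT
Fremdmaterial	SNOMED-CT	SCT-001341	Fremdmaterial
Fremdmaterial	Wingert	WGT-09387	FREMDMATERIAL
Kein	SNOMED-CT	SCT-000391	Kein
Kein	Wingert	WGT-02737	KEIN
suspekten	SNOMED-CT	SCT-000994	suspekten
suspekten	Wingert	WGT-06958	SUSPEKTEN
Lymphknoten	SNOMED-CT	SCT-001177	Lymphknoten
Lymphknoten	Wingert	WGT-08239	LYMPHKNOTEN
axillär beidseits	SNOMED-CT	SCT-001868	axillär beidseits
axillär beidseits	Wingert	WGT-13076	AXILLÄR BEIDSEITS
Suspekte	SNOMED-CT	SCT-000852	Suspekte
Suspekte	Wingert	WGT-05964	SUSPEKTE
Vergrößerte	SNOMED-CT	SCT-001419	Vergrößerte
Vergrößerte	Wingert	WGT-09933	VERGRÖßERTE
links axillär	SNOMED-CT	SCT-001457	links axillär
links axillär	Wingert	WGT-10199	LINKS AXILLÄR
rechts axillär	SNOMED-CT	SCT-001561	rechts axillär
rechts axillär	Wingert	WGT-10927	RECHTS AXILLÄR
ACR Typ	SNOMED-CT	SCT-000563	ACR Typ
ACR Typ	Wingert	WGT-03941	ACR TYP
A	SNOMED-CT	SCT-000065	A
A	Wingert	WGT-00455	A
B	SNOMED-CT	SCT-000066	B
B	Wingert	WGT-00462	B
C	SNOMED-CT	SCT-000067	C
C	Wingert	WGT-00469	C
D	SNOMED-CT	SCT-000068	D
D	Wingert	WGT-00476	D
Sonst kein	SNOMED-CT	SCT-000990	Sonst kein
Sonst kein	Wingert	WGT-06930	SONST KEIN
Malignität	SNOMED-CT	SCT-001165	Malignität
Malignität	Wingert	WGT-08155	MALIGNITÄT
Kontrolle	SNOMED-CT	SCT-000954	Kontrolle
Kontrolle	Wingert	WGT-06678	KONTROLLE
Verlaufskontrolle	SNOMED-CT	SCT-001826	Verlaufskontrolle
Verlaufskontrolle	Wingert	WGT-12782	VERLAUFSKONTROLLE
6 Monaten	SNOMED-CT	SCT-000808	6 Monaten
6 Monaten	Wingert	WGT-05656	6 MONATEN
12 Monaten	SNOMED-CT	SCT-000853	12 Monaten
12 Monaten	Wingert	WGT-05971	12 MONATEN
24 Monaten	SNOMED-CT	SCT-000856	24 Monaten
24 Monaten	Wingert	WGT-05992	24 MONATEN
mammographisch	SNOMED-CT	SCT-001488	mammographisch
mammographisch	Wingert	WGT-10416	MAMMOGRAPHISCH
sonographisch	SNOMED-CT	SCT-001400	sonographisch
sonographisch	Wingert	WGT-09800	SONOGRAPHISCH
BI-RADS	SNOMED-CT	SCT-000482	BI-RADS
BI-RADS	Wingert	WGT-03374	BI-RADS
0	SNOMED-CT	SCT-000048	0
0	Wingert	WGT-00336	0
1	SNOMED-CT	SCT-000049	1
1	Wingert	WGT-00343	1
2	SNOMED-CT	SCT-000050	2
2	Wingert	WGT-00350	2
3	SNOMED-CT	SCT-000051	3
3	Wingert	WGT-00357	3
4	SNOMED-CT	SCT-000052	4
4	Wingert	WGT-00364	4
5	SNOMED-CT	SCT-000053	5
5	Wingert	WGT-00371	5
6	SNOMED-CT	SCT-000054	6
6	Wingert	WGT-00378	6
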