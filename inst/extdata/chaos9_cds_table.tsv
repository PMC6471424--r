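start	stop	locus_tag	length	direction	gene	product
100	669	ChaoS9_005	570	+	-	HTH domain protein
656	2302	ChaoS9_010	1647	+	terL	terminase large subunit TerL
2316	3944	ChaoS9_015	1629	+	por	portal protein Por
3937	4083	ChaoS9_020	147	+	-	CxxC motif protein
4086	5273	ChaoS9_025	1188	+	-	putative phage head assembly protein, SPP1_gp7 family
5384	7300	ChaoS9_030	1917	+	-	probable prohead protease protein
7303	7755	ChaoS9_035	453	+	-	uncharacterized protein
7801	8928	ChaoS9_040	1128	+	-	major capsid protein MCP
8944	9363	ChaoS9_045	420	+	-	uncharacterized protein
9398	9784	ChaoS9_050	387	+	-	uncharacterized protein
9781	10191	ChaoS9_055	411	+	hco	head closure protein Hco, type 1
10188	10421	ChaoS9_060	234	+	-	uncharacterized protein
10414	10701	ChaoS9_065	288	+	-	uncharacterized protein
10703	11149	ChaoS9_070	447	+	nep	putative neck protein Nep, type 1
11156	11746	ChaoS9_075	591	+	tco	tail completion protein Tco, type 1
11767	13071	ChaoS9_080	1305	+	-	tail sheath protein
13082	13480	ChaoS9_085	399	+	-	predicted tail tube protein
13492	13932	ChaoS9_090	441	+	-	uncharacterized protein
13935	14144	ChaoS9_095	210	+	-	uncharacterized protein
14147	16891	ChaoS9_100	2745	+	tpm	tape-measure tail protein Tpm
16895	17422	ChaoS9_105	528	+	-	uncharacterized protein
17423	17767	ChaoS9_110	345	+	-	uncharacterized protein
17771	18604	ChaoS9_115	834	+	-	uncharacterized protein
18644	18787	ChaoS9_120	144	+	-	CxxC motif protein
18784	19335	ChaoS9_125	552	+	-	uncharacterized protein
19338	19700	ChaoS9_130	363	+	-	virus-related protein
19697	20062	ChaoS9_135	366	+	-	uncharacterized protein
20069	21328	ChaoS9_140	1260	+	bpj	baseplate J family protein Bpj
21321	21929	ChaoS9_145	609	+	-	uncharacterized protein
21933	22517	ChaoS9_150	585	+	-	uncharacterized protein
22514	23122	ChaoS9_155	609	+	-	uncharacterized protein
23115	24698	ChaoS9_160	1584	+	-	repeat-containing tail fiber protein
24702	24986	ChaoS9_165	285	+	-	uncharacterized protein
25024	25698	ChaoS9_170	675	+	int1	tyrosine integrase/recombinase Int1
25709	25996	ChaoS9_175	288	-	-	uncharacterized protein
25999	26145	ChaoS9_180	147	-	-	repeat-containing tail fiber protein (C-term) (nonfunctional)^9^
26199	27455	ChaoS9_185	1257	-	tnpB	IS1341-type transposase TnpB
27457	27849	ChaoS9_190	393	-	tnpA	IS200-type transposase TnpA
27906	28820	ChaoS9_195	915	-	-	repeat-containing tail fiber protein (N-term) (nonfunctional)
28854	29579	ChaoS9_200	726	+	-	transmembrane domain protein
29589	29861	ChaoS9_205	273	-	-	HTH domain protein
29933	30241	ChaoS9_210	309	-	-	uncharacterized protein
30238	30813	ChaoS9_215	576	-	-	glutamine amidotransferase domain protein, class-II
30818	31891	ChaoS9_220	1074	-	-	uncharacterized protein
32030	32266	ChaoS9_225	237	+	-	uncharacterized protein
32339	32584	ChaoS9_230	246	+	-	uncharacterized protein
32581	33009	ChaoS9_235	429	+	-	VapC family toxin
33098	33448	ChaoS9_240	351	+	-	uncharacterized protein
33457	34059	ChaoS9_245	603	-	int2	tyrosine integrase/recombinase Int2
34241	34432	ChaoS9_250	192	-	-	uncharacterized protein
34507	35055	ChaoS9_255	549	-	-	uncharacterized protein
35048	35902	ChaoS9_260	855	-	-	Plasmid partition protein ParA
35976	36440	ChaoS9_265	465	-	-	transmembrane domain protein
36460	38241	ChaoS9_270	1782	-	-	uncharacterized protein
38243	38857	ChaoS9_275	615	-	-	uncharacterized protein
38850	39080	ChaoS9_280	231	-	-	CxxC motif protein
39073	39240	ChaoS9_285	168	-	-	transmembrane domain protein
39233	40492	ChaoS9_290	1260	-	-	uncharacterized protein
40485	40673	ChaoS9_295	189	-	-	CxxC motif protein
40663	41181	ChaoS9_300	519	-	-	uncharacterized protein
41174	41611	ChaoS9_305	438	-	-	HNH-type endonuclease/MarR family transcription regulator
41613	41870	ChaoS9_310	258	-	-	HTH domain protein
41997	42602	ChaoS9_315	606	+	-	uncharacterized protein
42605	43051	ChaoS9_320	447	+	-	uncharacterized protein
43044	43250	ChaoS9_325	207	+	-	uncharacterized protein
43250	43621	ChaoS9_330	372	+	-	uncharacterized protein
43621	44127	ChaoS9_335	507	+	-	uncharacterized protein
44124	44255	ChaoS9_340	132	+	-	CxxC motif protein
44342	45400	ChaoS9_345	1059	+	orc1	Orc1-type DNA replication protein
45482	45709	ChaoS9_350	228	-	-	uncharacterized protein
45837	45992	ChaoS9_355	156	+	-	uncharacterized protein
46369	46905	ChaoS9_360	537	+	-	uncharacterized protein
46902	47177	ChaoS9_365	276	+	-	uncharacterized protein
47179	47979	ChaoS9_370	801	+	-	zinc-finger domain protein
47976	48068	ChaoS9_375	93	+	-	uncharacterized protein
48065	48397	ChaoS9_380	333	+	-	uncharacterized protein
48394	51690	ChaoS9_385	3297	+	repH	plasmid replication protein RepH
51683	51925	ChaoS9_390	243	+	-	MarR family transcription regulator
51932	52591	ChaoS9_395	660	+	-	CxxC motif protein
53208	53453	ChaoS9_400	246	+	-	transmembrane domain protein
53446	53769	ChaoS9_405	324	+	-	transmembrane domain protein
53766	54455	ChaoS9_410	690	+	-	uncharacterized protein
54460	54705	ChaoS9_415	246	+	-	DUF217 domain protein
54734	54922	ChaoS9_420	189	+	-	CxxC motif protein
54915	63	ChaoS9_425	294	+	terS	terminase small subunit TerS
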