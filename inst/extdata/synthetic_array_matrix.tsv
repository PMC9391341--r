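gene_id	S0001	S0002	S0003	S0004	S0005	S0006	S0007	S0008
UP01	8.75305729443341	10.519427655131855	9.449376028102352	10.180449407843156	10.456011570994232	11.622471955514602	11.351496325531455	12.055698919355898
UP02	8.540405073690057	9.38317127619312	9.032587083762008	9.378918404357258	10.23302081761725	10.63215117255417	11.206758358755785	11.722932728479472
UP03	7.585402557728981	8.357227885457371	8.075816357202893	8.02633440070763	10.586584912154656	9.974840476048302	9.780163159904678	10.994550920716318
UP04	8.282807266087023	8.018305615451558	8.614531061447392	8.422167608108744	9.854679635139654	9.150032124802472	8.533539408618314	10.721790268533121
UP05	9.48765823330672	10.810096752646247	10.60107371013811	10.221557234558906	10.905317977384602	11.351299500821638	12.282504424279333	11.756051424384008
UP06	10.133330009009857	10.124088298230799	9.495735446189121	10.793082536808223	10.014551714717589	12.116431508718538	12.362161077910283	13.358378203452999
UP07	8.970636656630337	8.054218729346285	8.809190924642701	9.105352869402994	10.518367139985648	11.102025117929665	11.375342634875427	10.99364394042053
UP08	7.564817146168468	8.416767615896122	7.809952237353725	8.103681468899724	9.208343939403287	9.431072910636184	10.29469187667892	10.412380613908335
UP09	5.877301347950315	6.658536659775809	6.737936778161988	6.718311644282097	7.358196546113537	7.629433698980235	8.088440829606476	8.075724673182993
UP10	6.532155078847709	5.508566751171133	7.4838635220254215	7.417881689359974	8.015873771144276	8.358996250845221	9.081798018421493	8.868547119957245
UP11	5.055881545257575	6.307771691248551	7.186572894989753	5.847154567113834	7.9133603330520295	6.999548682755863	7.3900937895237835	8.830696728693894
UP12	8.701031387996391	8.349269254569327	9.513572865830902	9.610265761735564	10.253868006074116	9.98253012989683	11.675131295924556	11.263587433765332
DN01	9.495972434206552	9.646217819013337	9.179738273680506	8.583297040877447	7.694275877876665	8.22417873559638	7.091468533753227	7.787251041051182
DN02	9.425941747353045	8.727166752700763	7.912241200317933	8.117768153245573	7.668752153268065	7.670516507298033	6.178758783728908	6.3266578761117716
DN03	2.490140204187251	3.436651390317572	1.8658169589407212	3.593845215112073	1.346541465186379	2.4306192158018773	0.877693112260218	1.2505862555728258
DN04	7.843053113781504	7.871454423352407	7.37488431191917	7.016203677163827	5.909614157589978	6.767794600398738	5.673478931795278	5.016743728027834
DN05	6.769621717181047	7.565736970492175	5.915157609626416	5.664576256562081	5.121824642543055	5.935380735735445	4.338760999022125	4.70503376582978
DN06	9.015400678161686	9.2730568026023	8.668583399679333	8.605230852166454	6.26688817451069	7.623752259757281	6.686816652056581	6.626755903227115
DN07	5.910335617678491	5.321410993437258	4.719856704271095	5.4137815456280105	4.6505152197243	5.437337262947491	3.2388782218053525	3.893028116678334
DN08	5.953018655049788	5.240634351576773	3.8237851235895364	4.4927088871778755	4.529036203452359	2.774437024615158	3.0667535997514728	2.4333409577398606
BG0001	9.432695418583718	9.338360111777956	9.06327990443515	10.23583394924325	9.525703289266053	9.961059681575977	10.383524166179873	9.840601324839117
BG0002	8.090698898214354	9.2194839185299209	9.035960399469257	8.10030169809298	8.93650977089275	8.96123659503567	8.811468769369196	8.55178609602642
BG0003	9.240681969345323	10.246011719799727	9.21352878641372	9.415802649952377	9.319290261698644	9.425157901844738	9.454171739733512	10.078761539546763
BG0004	7.166760828189743	7.053006980683395	7.666088350222702	8.802201080010818	7.784302431857136	8.033215092573057	7.4941001329398	7.552438713429738
BG0005	8.255201536732477	8.92005468172096	8.28316312871943	9.277676234861708	8.794714471600296	9.356922943318805	8.579655605224309	7.5752667826157225
BG0006	4.967715918271493	6.489558529112212	4.769337239034285	6.300123192219714	6.2625400037697165	5.429482843731886	5.728161428713818	6.238725414386297
BG0007	8.270447203779606	7.9813239903404	8.775097031258806	8.94028375417354	8.443766043304898	7.69673369284021	7.790922771563303	7.845331405363352
BG0008	8.907516191882014	9.149452943118753	9.292006384604065	9.346235419546929	9.110001818396288	9.349143043281758	8.769221494256286	9.641429971779257
BG0009	5.416618429710553	5.040948179763246	4.7840210487914705	5.6024453222401425	5.274025370504782	5.606695637662435	4.9554551595213665	5.436356530694441
BG0010	7.819569001432095	8.494174470984742	8.289437614151923	8.610988367603612	7.646661831509111	8.301544628603308	7.3775193925078595	8.548367863593544
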