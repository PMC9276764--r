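locus_id	block_id	scaffold	position_bp	s	p0
B001	B001	scf1	2000000	0.292792538956162	0.388056936960126
B005	B005	scf1	4000000	0.277133559914861	0.522325203888608
B009	B009	scf1	6000000	0.137979163804804	0.211542294417483
B013	B013	scf1	8000000	0.144725171893245	0.316623402218988
B017	B017	scf1	10000000	0.126210542000748	0.270681195766138
B021	B021	scf1	12000000	0.0928233191645354	0.281012202946674
B025	B025	scf1	14000000	0.103328991497004	0.188849838305771
B029	B029	scf1	16000000	0.174158273284553	0.145873775221153
B033	B033	scf1	18000000	0.182179415685734	0.0904466229887825
B037	B037	scf1	20000000	0.0783091576801549	0.255555367334824
B041	B041	scf1	22000000	0.116661888664654	0.334806876229961
B045	B045	scf1	24000000	0.148141577310633	0.358822482955662
B049	B049	scf1	26000000	0.11827820197131	0.389626634056286
B053	B053	scf1	28000000	0.144680512750417	0.254095875139275
B057	B057	scf1	30000000	0.173127099796187	0.26521777489661
B061	B061	scf1	32000000	0.0759847149649323	0.163032708131769
B065	B065	scf1	34000000	0.117393590668544	0.235716147827892
B069	B069	scf1	36000000	0.180415776077327	0.322921227646599
B073	B073	scf1	38000000	0.160065440509096	0.354419075727786
B077	B077	scf1	40000000	0.291304249546941	0.468304177036927
B081	B081	scf1	42000000	0.121520698384105	0.306123400088215
B085	B085	scf1	44000000	0.132215138661012	0.0789117358972656
B089	B089	scf1	46000000	0.166825016836095	0.328187155735072
B093	B093	scf1	48000000	0.141830002461807	0.34774566915779
B097	B097	scf1	50000000	0.152033723460641	0.201298145328199
B101	B101	scf1	52000000	0.0744014372387155	0.361881066580634
B105	B105	scf1	54000000	0.19974953487734	0.254789155385988
B109	B109	scf1	56000000	0.124922344109423	0.51244768137714
B113	B113	scf1	58000000	0.202751905548992	0.257842199454229
B117	B117	scf1	60000000	0.13129611133342	0.449735173240151
B121	B121	scf1	62000000	0.195212782825759	0.336288865445194
B002	B002	scf2	2000000	0.152891346681298	0.132688583337588
B006	B006	scf2	4000000	0.0964230897492112	0.274850807592201
B010	B010	scf2	6000000	0.294759362515159	0.31175319607896
B014	B014	scf2	8000000	0.0710591553594671	0.415796852282169
B018	B018	scf2	10000000	0.129592828714088	0.228638202458742
B022	B022	scf2	12000000	0.109778661453968	0.349008807023387
B026	B026	scf2	14000000	0.12395387864607	0.191125474545989
B030	B030	scf2	16000000	0.121995375499409	0.335440282089148
B034	B034	scf2	18000000	0.204915928049564	0.531159135627719
B038	B038	scf2	20000000	0.138477613997462	0.540683557232428
B042	B042	scf2	22000000	0.165530351780036	0.258312437558663
B046	B046	scf2	24000000	0.232971358328377	0.297472097269403
B050	B050	scf2	26000000	0.0410401914595354	0.290872889557132
B054	B054	scf2	28000000	0.113094583965265	0.322218267590104
B058	B058	scf2	30000000	0.138564839385504	0.171623134123923
B062	B062	scf2	32000000	0.0514520136323057	0.318192110307102
B066	B066	scf2	34000000	0.19766738688283	0.383774576941223
B070	B070	scf2	36000000	0.22409114451682	0.266773016334847
B074	B074	scf2	38000000	0.0775579784292009	0.312876921352188
B078	B078	scf2	40000000	0.176553915634158	0.376840307918013
B082	B082	scf2	42000000	0.0988741667748896	0.290777430072939
B086	B086	scf2	44000000	0.11170324935309	0.358705176606443
B090	B090	scf2	46000000	0.116806572712622	0.315047882028636
B094	B094	scf2	48000000	0.122063137252795	0.269602086414496
B098	B098	scf2	50000000	0.177199878498107	0.462472780488253
B102	B102	scf2	52000000	0.181090787472781	0.230353507457128
B106	B106	scf2	54000000	0.0772604507813355	0.306136055205723
B110	B110	scf2	56000000	0.163121145396516	0.215432596930005
B114	B114	scf2	58000000	0.107175610898375	0.128469299166261
B118	B118	scf2	60000000	0.0644087604657909	0.270883681409641
B003	B003	scf3	2000000	0.151840491075207	0.195214245232208
B007	B007	scf3	4000000	0.0978089090349462	0.325613534042685
B011	B011	scf3	6000000	0.121436735747962	0.26236903108024
B015	B015	scf3	8000000	0.108505554283648	0.370358881881547
B019	B019	scf3	10000000	0.0688297944814084	0.181574733028922
B023	B023	scf3	12000000	0.0790136859229238	0.217986737065947
B027	B027	scf3	14000000	0.0707083357767523	0.152987803709449
B031	B031	scf3	16000000	0.107816214260658	0.427751044495917
B035	B035	scf3	18000000	0.128547718921409	0.34120242197486
B039	B039	scf3	20000000	0.18987125613438	0.184947232175021
B043	B043	scf3	22000000	0.153964893635475	0.292607254207752
B047	B047	scf3	24000000	0.113222159611938	0.377333966256664
B051	B051	scf3	26000000	0.107777964254161	0.113441190356329
B055	B055	scf3	28000000	0.166155243313755	0.255295363979168
B059	B059	scf3	30000000	0.0877301676710086	0.212779687318806
B063	B063	scf3	32000000	0.116189116254718	0.351071927502352
B067	B067	scf3	34000000	0.0689185031422825	0.321835969015071
B071	B071	scf3	36000000	0.178562297508475	0.283166070580534
B075	B075	scf3	38000000	0.0567905902171055	0.351264092939823
B079	B079	scf3	40000000	0.188198817185841	0.222643703366178
B083	B083	scf3	42000000	0.36822800442031	0.439304598049903
B087	B087	scf3	44000000	0.0471426685375833	0.349513070801184
B091	B091	scf3	46000000	0.0567019683383925	0.216243669142197
B095	B095	scf3	48000000	0.0452087094988412	0.505697493526732
B099	B099	scf3	50000000	0.305914275817262	0.309584517223935
B103	B103	scf3	52000000	0.0561418556440468	0.249757724321543
B107	B107	scf3	54000000	0.112963094238039	0.124179936279089
B111	B111	scf3	56000000	0.203976285272544	0.473764250950237
B115	B115	scf3	58000000	0.11093481020439	0.26446327386687
B119	B119	scf3	60000000	0.0539273495174138	0.445912357930156
B004	B004	scf4	2000000	0.132464197545553	0.166546964594611
B008	B008	scf4	4000000	0.0463563147433785	0.219451390266992
B012	B012	scf4	6000000	0.0890488877741247	0.401875148185282
B016	B016	scf4	8000000	0.23977100497262	0.302133972824704
B020	B020	scf4	10000000	0.100538119677381	0.417330925959832
B024	B024	scf4	12000000	0.0858822259605757	0.213718965718672
B028	B028	scf4	14000000	0.0483557738740747	0.260881251117782
B032	B032	scf4	16000000	0.189312603662676	0.278656285564631
B036	B036	scf4	18000000	0.0899763593161747	0.433073669652773
B040	B040	scf4	20000000	0.159685627668057	0.190013800800469
B044	B044	scf4	22000000	0.0592400334099606	0.124074347830035
B048	B048	scf4	24000000	0.0434365698255599	0.159609334094775
B052	B052	scf4	26000000	0.0768904529154192	0.420850725300379
B056	B056	scf4	28000000	0.124808099748165	0.360628179795567
B060	B060	scf4	30000000	0.136731580856802	0.539630892565045
B064	B064	scf4	32000000	0.187051094513095	0.0835069542281204
B068	B068	scf4	34000000	0.126328890275118	0.232974284428907
B072	B072	scf4	36000000	0.161254428837367	0.220958440337129
B076	B076	scf4	38000000	0.166511091721161	0.188168305371934
B080	B080	scf4	40000000	0.0980488935157786	0.25665587202915
B084	B084	scf4	42000000	0.222844267182962	0.425179029924805
B088	B088	scf4	44000000	0.109609353743436	0.277138198679814
B092	B092	scf4	46000000	0.0977987671339817	0.193572546660721
B096	B096	scf4	48000000	0.156573074452052	0.320976443709466
B100	B100	scf4	50000000	0.0911958703526994	0.369176304380502
B104	B104	scf4	52000000	0.0921992156486446	0.27515336410042
B108	B108	scf4	54000000	0.234125123765782	0.311873584148827
B112	B112	scf4	56000000	0.11262406193279	0.43503514988265
B116	B116	scf4	58000000	0.0674140953120306	0.258479874564699
B120	B120	scf4	60000000	0.156039510288655	0.324812516575579
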