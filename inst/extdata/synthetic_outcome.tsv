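snp_id	effect_allele	other_allele	beta	se	pvalue	n	trait_id	chrom	pos	eaf
rs000001	G	A	-0.05372245820141155	0.019578437202980595	0.006070284289311571	314708	outcome	1	20000001	0.46592241739854223
rs000002	C	T	0.012117121383825737	0.01955770825492568	0.5355492708125426	314708	outcome	2	20000002	0.4748301653191448
rs000003	A	G	0.16327175138436312	0.023794839445984164	6.8071853749440336e-12	314708	outcome	3	20000003	0.21445581391453744
rs000004	G	T	0.11447089792669193	0.01971512064648394	6.388796043629807e-9	314708	outcome	4	20000004	0.43217905042693017
rs000005	A	C	-0.06799950564876128	0.020388212719913	8.522696628610829e-4	314708	outcome	5	20000005	0.3566982075572014
rs000006	C	A	0.01372440117951141	0.021161685218017576	0.5166295811083187	314708	outcome	6	20000006	0.3076383796520531
rs000007	C	A	0.07257508142660025	0.01998161026495661	2.8113096222966155e-4	314708	outcome	7	20000007	0.39463532585650685
rs000008	A	C	-0.0033201970982709977	0.02706732624305574	0.902372862474552	314708	outcome	8	20000008	0.1538666388951242
rs000009	G	T	-0.06218211034029459	0.020312635363571415	0.0022041296729080778	314708	outcome	9	20000009	0.3627969161607325
rs000010	C	A	-0.10440525239610221	0.02010043502646939	2.0562550871376714e-7	314708	outcome	10	20000010	0.3820259136147798
rs000011	G	C	0.04596188373628636	0.021679002841110538	0.03399671918585434	314708	outcome	11	20000011	0.28309671049937607
rs000012	G	A	0.0034017846202240506	0.020045564613821863	0.8652440219002666	314708	outcome	12	20000012	0.3876449006609619
rs000013	C	T	0.0809197370538641	0.019559642374806712	3.517588423033982e-5	314708	outcome	13	20000013	0.4738688988611103
rs000014	G	A	-0.0063808509413354406	0.024317685464550133	0.7930165510080693	314708	outcome	14	20000014	0.20217152973636987
rs000015	G	T	0.009590965914274451	0.02163712395403253	0.657574530961483	314708	outcome	15	20000015	0.2849171290174127
rs000016	T	C	-0.02388719792100979	0.019555442058280866	0.22189240330554832	314708	outcome	16	20000016	0.47600580910220747
rs000017	A	C	-0.06604604040135675	0.0195358760941198	7.228656707605793e-4	314708	outcome	17	20000017	0.49129057135432963
rs000018	T	A	-0.020288045964290735	0.027580999367799636	0.46198601878767487	314708	outcome	18	20000018	0.1469949446618557
rs000019	A	G	0.024982802130646593	0.021523324038799897	0.2457510709554613	314708	outcome	19	20000019	0.2899988326244056
rs000020	T	G	-0.03536340932008693	0.02086626509673614	0.09012006812918347	314708	outcome	20	20000020	0.32413309849798677
rs000021	A	G	-0.06708587509097211	0.019590735103896147	6.162324359080799e-4	314708	outcome	21	20000021	0.4616125549189747
rs000022	T	C	-0.011251888093949386	0.0269519461654843	0.6763276321258049	314708	outcome	22	40000022	0.15548406708985568
rs000023	T	A	-0.049778539249302686	0.01953368343668047	0.010823577420471141	314708	outcome	1	40000023	0.4955566915683448
rs000024	T	C	-0.040703711646987585	0.01955071467018117	0.037346563981415	314708	outcome	2	40000024	0.4786672930233181
rs000025	G	T	0.013335097727218838	0.028763130959675066	0.6429216432227766	314708	outcome	3	40000025	0.132975023239851
rs000026	C	T	0.03057672293173933	0.021199312461683356	0.1492050633731117	314708	outcome	4	40000026	0.3056847137399018
rs000027	G	A	-0.021017030396573346	0.022376145701758273	0.3475969998691025	314708	outcome	5	40000027	0.25608138684183357
rs000028	A	T	-0.017304268473066823	0.019588687959388635	0.3770306261928477	314708	outcome	6	40000028	0.46229525236412883
rs000029	C	A	0.023451210918883032	0.021780535902144675	0.2816120982200505	314708	outcome	7	40000029	0.2787878512404859
rs000030	A	G	0.02947337782849502	0.019703219434473188	0.13468855437764962	314708	outcome	8	40000030	0.43440170399844646
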