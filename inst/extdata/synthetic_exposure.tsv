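snp_id	effect_allele	other_allele	beta	se	pvalue	n	trait_id	chrom	pos	eaf
rs000001	G	A	0.06967638804130309	0.010467099644424209	2.8003563466667457e-11	18340	exposure	1	20000001	0.46592241739854223
rs000002	C	T	-0.02039320185084141	0.010456017454228668	0.05113090616883093	18340	exposure	2	20000002	0.4748301653191448
rs000003	A	G	-0.259745820622858	0.01272128888133497	1.1523237106162911e-92	18340	exposure	3	20000003	0.21445581391453744
rs000004	G	T	-0.25338292904607923	0.010540173874407935	1.0690676574374227e-127	18340	exposure	4	20000004	0.43217905042693017
rs000005	A	C	0.12002369533167721	0.010900024955952969	3.3701803072909844e-28	18340	exposure	5	20000005	0.3566982075572014
rs000006	G	T	-0.013549785409960147	0.01131354180747418	0.2310491001168203	18340	exposure	6	20000006	0.3076383796520531
rs000007	C	A	-0.1753755600927075	0.010682645582534536	1.4485821810791918e-60	18340	exposure	7	20000007	0.39463532585650685
rs000008	A	C	-0.015911931311710748	0.014470838400271862	0.271512544614221	18340	exposure	8	20000008	0.1538666388951242
rs000009	G	T	0.12015457952095042	0.010859619498076633	1.8682221838688114e-28	18340	exposure	9	20000009	0.3627969161607325
rs000010	C	A	0.17668488223324758	0.010746172135041487	9.625001011013015e-61	18340	exposure	10	20000010	0.3820259136147798
rs000011	G	C	-0.03595380047608635	0.011590112151296433	0.0019214667537645128	18340	exposure	11	20000011	0.28309671049937607
rs000012	G	A	-0.02805399063239507	0.010716837103304386	0.008851186012109005	18340	exposure	12	20000012	0.3876449006609619
rs000013	C	T	-0.1782274048060638	0.010457051480862619	3.889500578160598e-65	18340	exposure	13	20000013	0.4738688988611103
rs000014	G	A	0.0581439982799334	0.013000814837277323	7.737012084086369e-6	18340	exposure	14	20000014	0.20217152973636987
rs000015	G	T	-0.054493444132084276	0.011567722699089475	2.4672367763546415e-6	18340	exposure	15	20000015	0.2849171290174127
rs000016	T	C	0.060099318812801145	0.010454805891433884	9.004541206151416e-9	18340	exposure	16	20000016	0.47600580910220747
rs000017	A	C	0.06551040877137199	0.01044434546017526	3.556787184972433e-10	18340	exposure	17	20000017	0.49129057135432963
rs000018	T	A	0.11310004108575746	0.014745460308323776	1.7178181900540687e-14	18340	exposure	18	20000018	0.1469949446618557
rs000019	A	G	-0.04488529290595203	0.011506882549290099	9.59013097212855e-5	18340	exposure	19	20000019	0.2899988326244056
rs000020	T	G	0.038103992393577785	0.01115560316230234	6.362250859306089e-4	18340	exposure	20	20000020	0.32413309849798677
rs000021	A	G	-0.009015661277161016	0.010473674395665373	0.38935228860541254	18340	exposure	21	20000021	0.4616125549189747
rs000022	T	C	-0.016307396326760124	0.014409153457985569	0.25774431420995714	18340	exposure	22	40000022	0.15548406708985568
rs000023	T	A	-0.015238824551921501	0.010443173213194273	0.14450621684088547	18340	exposure	1	40000023	0.4955566915683448
rs000024	T	C	8.359999229747212e-4	0.010452278516966538	0.9362511320068203	18340	exposure	2	40000024	0.4786672930233181
rs000025	G	T	0.010044621032098867	0.015377456061442325	0.5136245529157597	18340	exposure	3	40000025	0.132975023239851
rs000026	C	T	0.013611331112705823	0.011333658229674352	0.22976463262571295	18340	exposure	4	40000026	0.3056847137399018
rs000027	G	A	0.012498170618850451	0.011962821357508657	0.2961380266726572	18340	exposure	5	40000027	0.25608138684183357
rs000028	A	T	-0.010506182753909833	0.010472579943369486	0.31576020184643017	18340	exposure	6	40000028	0.46229525236412883
rs000029	C	A	0.021524451838836868	0.011644394148170317	0.06453266017753005	18340	exposure	7	40000029	0.2787878512404859
rs000030	A	G	-0.007023665202715377	0.010533811202519752	0.5049168804241714	18340	exposure	8	40000030	0.43440170399844646
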