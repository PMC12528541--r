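snp_id	effect_allele	other_allele	beta	se	pvalue	n	trait_id	chrom	pos	eaf
rs000001	G	A	0.014297221261113439	0.015560127165365409	0.3581808128506604	8299	mediator	1	20000001	0.46592241739854223
rs000002	C	T	-0.012220031897613072	0.015543652660051489	0.43176494129230997	8299	mediator	2	20000002	0.4748301653191448
rs000003	A	G	-0.05517724511132213	0.01891114820965384	0.003526121904428524	8299	mediator	3	20000003	0.21445581391453744
rs000004	G	T	-0.04561654086192255	0.01566875747841145	0.0035992183839804997	8299	mediator	4	20000004	0.43217905042693017
rs000005	A	C	0.028201104358422966	0.01620370304878421	0.08178686096923116	8299	mediator	5	20000005	0.3566982075572014
rs000006	G	T	-0.006524125252238847	0.016818426803527402	0.6980787076271184	8299	mediator	6	20000006	0.3076383796520531
rs000007	C	A	-0.03373178322384502	0.015880552337658605	0.03366229841537829	8299	mediator	7	20000007	0.39463532585650685
rs000008	A	C	-0.013863830666845978	0.02151198453696096	0.5192706452259309	8299	mediator	8	20000008	0.1538666388951242
rs000009	G	T	0.016032128029722252	0.016143637310987828	0.32066479127695524	8299	mediator	9	20000009	0.3627969161607325
rs000010	C	A	0.011178309829006208	0.015974989313417405	0.48409083271884706	8299	mediator	10	20000010	0.3820259136147798
rs000011	G	C	-0.015153781170681016	0.017229569323063416	0.37911843891878405	8299	mediator	11	20000011	0.28309671049937607
rs000012	G	A	-0.013286887086342115	0.015931380592784608	0.4042768924148223	8299	mediator	12	20000012	0.3876449006609619
rs000013	C	T	0.006914463072658833	0.015545189818047808	0.6564660312575512	8299	mediator	13	20000013	0.4738688988611103
rs000014	G	A	-0.017169253247607902	0.01932668446785697	0.374341574462748	8299	mediator	14	20000014	0.20217152973636987
rs000015	G	T	-0.010375600879556569	0.017196285726332902	0.5462672951380294	8299	mediator	15	20000015	0.2849171290174127
rs000016	T	C	-0.014150241661782186	0.015541851581262135	0.36257971415284085	8299	mediator	16	20000016	0.47600580910220747
rs000017	A	C	-0.008804165451724974	0.015526301367151439	0.5706812505098198	8299	mediator	17	20000017	0.49129057135432963
rs000018	T	A	0.023332065144130342	0.021920230560868774	0.2871439861802248	8299	mediator	18	20000018	0.1469949446618557
rs000019	A	G	-0.029165986731271323	0.01710584228929708	0.08818869368758009	8299	mediator	19	20000019	0.2899988326244056
rs000020	T	G	0.010018381375627746	0.016583639184541806	0.5457689437571991	8299	mediator	20	20000020	0.32413309849798677
rs000021	A	G	0.14963716744831013	0.015569901025256738	7.207902288272738e-22	8299	mediator	21	20000021	0.4616125549189747
rs000022	T	C	0.027156753508646297	0.021420285252654037	0.20486745004006296	8299	mediator	22	40000022	0.15548406708985568
rs000023	T	A	0.09318850171454576	0.01552455873426239	1.9412206946351008e-9	8299	mediator	1	40000023	0.4955566915683448
rs000024	T	C	0.09145717886483479	0.015538094449922761	3.956612514386886e-9	8299	mediator	2	40000024	0.4786672930233181
rs000025	G	T	0.09060907863430182	0.022859739557683754	7.379794352167695e-5	8299	mediator	3	40000025	0.132975023239851
rs000026	C	T	-0.11561081276029155	0.016848331370998833	6.797187381371963e-12	8299	mediator	4	40000026	0.3056847137399018
rs000027	G	A	-0.019587514617259792	0.01778362945828473	0.2707073134011427	8299	mediator	5	40000027	0.25608138684183357
rs000028	A	T	0.07482315843630735	0.015568274039990622	1.5387939077998424e-6	8299	mediator	6	40000028	0.46229525236412883
rs000029	C	A	-0.09498528724030847	0.017310263574846677	4.08300116152527e-8	8299	mediator	7	40000029	0.2787878512404859
rs000030	A	G	-0.042592326310605735	0.015659298890354126	0.006529410455291886	8299	mediator	8	40000030	0.43440170399844646
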