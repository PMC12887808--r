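variant_id	chrom	pos	effect_allele	other_allele	eaf	beta	se	pval	n
v0001	1	1000	A	G	0.4266	0.0848336	0.0156443	6.219e-08	4000
v0002	1	2000	A	G	0.1944	0.0809068	0.0156495	2.456e-07	4000
v0003	1	3000	A	G	0.3562	0.0978476	0.0156253	4.198e-10	4000
v0004	1	4000	A	G	0.3642	0.126748	0.0155732	5.279e-16	4000
v0005	1	5000	A	G	0.2557	0.129599	0.0155673	1.144e-16	4000
v0006	1	6000	A	G	0.3656	0.170167	0.0154693	9.487e-28	4000
v0007	1	7000	A	G	0.2371	0.180072	0.0154413	6.3e-31	4000
v0008	1	8000	A	G	0.1864	0.180351	0.0154405	5.094e-31	4000
v0009	1	9000	A	G	0.4445	0.260269	0.0151526	7.393e-64	4000
v0010	1	10000	A	G	0.1036	0.237172	0.0152471	5.098e-53	4000
v0011	1	11000	A	G	0.4558	0.348201	0.0147043	4.035e-116	4000
v0012	1	12000	A	G	0.4789	0.402246	0.0143552	6.68e-158	4000
v0013	1	13000	A	G	0.3666	0.525514	0.0133217	9.363e-288	4000
v0014	1	14000	A	G	0.2821	0.436487	0.0141028	9.708e-189	4000
v0015	1	15000	A	G	0.2523	0.439733	0.0140776	7.464e-192	4000
v0016	1	16000	A	G	0.429	0.535117	0.0132257	2.573e-300	4000
v0017	1	17000	A	G	0.09964	0.298657	0.0149744	1.887e-84	4000
v0018	1	18000	A	G	0.4384	0.317728	0.0148759	6.175e-96	4000
v0019	1	19000	A	G	0.109	0.205644	0.0153612	5.161e-40	4000
v0020	1	20000	A	G	0.1829	0.20288	0.0153704	5.713e-39	4000
v0021	1	21000	A	G	0.07127	-0.0450665	0.0156855	0.004086	4000
v0022	1	22000	A	G	0.1004	-0.0191405	0.0156988	0.2228	4000
v0023	1	23000	A	G	0.3562	-0.0232841	0.0156974	0.1381	4000
v0024	1	24000	A	G	0.4325	-0.0276921	0.0156956	0.07775	4000
v0025	1	25000	A	G	0.4088	-0.0243955	0.015697	0.1202	4000
v0026	1	26000	A	G	0.1815	-0.0128014	0.0157004	0.4149	4000
v0027	1	27000	A	G	0.3269	-0.022409	0.0156977	0.1535	4000
v0028	1	28000	A	G	0.417	-0.00928101	0.015701	0.5545	4000
v0029	1	29000	A	G	0.05024	0.000699768	0.0157017	0.9645	4000
v0030	1	30000	A	G	0.05951	-0.0163236	0.0156996	0.2985	4000
v0031	1	31000	A	G	0.2485	-0.0272521	0.0156958	0.08259	4000
v0032	1	32000	A	G	0.1806	-0.0247406	0.0156968	0.1151	4000
v0033	1	33000	A	G	0.1293	-0.0169167	0.0156994	0.2813	4000
v0034	1	34000	A	G	0.488	-0.0185055	0.015699	0.2386	4000
v0035	1	35000	A	G	0.3538	-0.0149699	0.0156999	0.3404	4000
v0036	1	36000	A	G	0.3564	-0.0284167	0.0156953	0.07029	4000
v0037	1	37000	A	G	0.07436	-0.0240275	0.0156971	0.1259	4000
v0038	1	38000	A	G	0.4848	-0.0226207	0.0156976	0.1497	4000
v0039	1	39000	A	G	0.05996	-0.0128095	0.0157004	0.4146	4000
v0040	1	40000	A	G	0.3413	-0.000604022	0.0157017	0.9693	4000
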