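variant_id	chrom	pos	effect_allele	other_allele	eaf	beta	se	pval	n
v0001	1	1000	A	G	0.4266	0.0144437	0.0166458	0.3856	4000
v0002	1	2000	A	G	0.1944	0.00897919	0.0166468	0.5896	4000
v0003	1	3000	A	G	0.3562	0.00965764	0.0166467	0.5618	4000
v0004	1	4000	A	G	0.3642	0.0225896	0.0166435	0.1748	4000
v0005	1	5000	A	G	0.2557	0.0258219	0.0166423	0.1208	4000
v0006	1	6000	A	G	0.3656	0.0125007	0.0166462	0.4527	4000
v0007	1	7000	A	G	0.2371	0.000294495	0.0166474	0.9859	4000
v0008	1	8000	A	G	0.1864	0.0275742	0.0166416	0.09761	4000
v0009	1	9000	A	G	0.4445	0.0237144	0.0166431	0.1543	4000
v0010	1	10000	A	G	0.1036	0.0437447	0.016633	0.008571	4000
v0011	1	11000	A	G	0.4558	0.0714822	0.0166089	1.719e-05	4000
v0012	1	12000	A	G	0.4789	0.089225	0.0165874	7.916e-08	4000
v0013	1	13000	A	G	0.3666	0.122158	0.0165349	1.806e-13	4000
v0014	1	14000	A	G	0.2821	0.0923997	0.0165831	2.685e-08	4000
v0015	1	15000	A	G	0.2523	0.109492	0.016557	4.264e-11	4000
v0016	1	16000	A	G	0.429	0.133967	0.016512	6.493e-16	4000
v0017	1	17000	A	G	0.09964	0.0792492	0.0166001	1.87e-06	4000
v0018	1	18000	A	G	0.4384	0.0903522	0.0165859	5.415e-08	4000
v0019	1	19000	A	G	0.109	0.0630092	0.0166175	0.0001518	4000
v0020	1	20000	A	G	0.1829	0.0783585	0.0166012	2.438e-06	4000
v0021	1	21000	A	G	0.07127	0.00122033	0.0166473	0.9416	4000
v0022	1	22000	A	G	0.1004	0.0145411	0.0166458	0.3824	4000
v0023	1	23000	A	G	0.3562	0.00425304	0.0166472	0.7984	4000
v0024	1	24000	A	G	0.4325	0.0168606	0.0166452	0.3111	4000
v0025	1	25000	A	G	0.4088	0.0023111	0.0166473	0.8896	4000
v0026	1	26000	A	G	0.1815	-0.000827121	0.0166474	0.9604	4000
v0027	1	27000	A	G	0.3269	0.00405223	0.0166472	0.8077	4000
v0028	1	28000	A	G	0.417	0.00366614	0.0166473	0.8257	4000
v0029	1	29000	A	G	0.05024	0.0298981	0.0166406	0.07246	4000
v0030	1	30000	A	G	0.05951	0.0319506	0.0166397	0.05491	4000
v0031	1	31000	A	G	0.2485	0.0311078	0.0166401	0.06163	4000
v0032	1	32000	A	G	0.1806	0.0360311	0.0166376	0.0304	4000
v0033	1	33000	A	G	0.1293	0.0367947	0.0166372	0.02705	4000
v0034	1	34000	A	G	0.488	0.0356981	0.0166378	0.03196	4000
v0035	1	35000	A	G	0.3538	0.0305131	0.0166404	0.06678	4000
v0036	1	36000	A	G	0.3564	0.0233704	0.0166433	0.1603	4000
v0037	1	37000	A	G	0.07436	0.0465593	0.0166311	0.005142	4000
v0038	1	38000	A	G	0.4848	0.0302045	0.0166405	0.06958	4000
v0039	1	39000	A	G	0.05996	0.0316906	0.0166398	0.05692	4000
v0040	1	40000	A	G	0.3413	0.0123021	0.0166462	0.4599	4000
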