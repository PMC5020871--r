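chromosome	length_bp	number	n50	count_ge_n50	n90	count_ge_n90	max_contig
chr01	41505150	1800	249739	47	31557	200	1560848
chr02	34325857	1467	266730	41	37069	159	884689
chr03	35724790	1154	287031	38	50086	136	1808391
chr04	29991449	2303	151932	53	6534	451	981333
chr05	27896270	1635	188526	42	10219	243	973308
chr06	29165153	1755	183332	47	13724	210	749307
chr07	27477590	1958	151089	48	8298	277	1065432
chr08	26789663	1556	173772	48	14332	219	739850
chr09	21657142	1190	218997	24	15452	147	1087529
chr10	21689031	1663	129607	45	6829	278	871567
chr11	27003295	2130	126457	60	5702	366	527948
chr12	24887049	2048	141176	43	5320	354	628599
chrUn	1921273	1382	1904	239	593	1028	20713
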