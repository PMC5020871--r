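chromosome	length_bp	number	n50	count_ge_n50	n90	count_ge_n90	max_contig
chr01	41467158	2360	146312	79	14985	367	659130
chr02	34737720	1760	162664	68	19298	266	616724
chr03	35174344	1580	180406	62	27156	238	526233
chr04	32237781	2758	83872	88	5715	629	652894
chr05	27841841	1926	113801	68	9194	372	530915
chr06	28862311	2744	59335	114	5123	737	447621
chr07	27358412	2464	100207	73	4994	487	530282
chr08	25940982	1999	93823	73	7300	401	587588
chr09	21608822	1703	113836	52	6627	312	686925
chr10	21690036	2087	80081	72	4308	482	376283
chr11	27926507	2880	79019	95	3592	713	598709
chr12	25125875	2559	80004	85	3845	585	367314
chrUn	1784506	1316	1723	257	603	990	20724
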