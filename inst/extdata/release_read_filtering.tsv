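library	raw_reads	raw_bp	clean_reads	clean_bp
ZS97_short	338293782	34167671982	299201824	29652703238
ZS97_5kb	436436254	33169155304	345177784	25846914440
ZS97_10kb	396565650	30138989400	327334042	24554200308
MH63_short	382103532	38592456732	341947062	33482334975
MH63_5kb	267288070	20313893320	214879076	16135182511
MH63_10kb	198185740	10107472740	173925986	8866402830
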