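key	value
zs97_library_clones	36864
zs97_tagged_clones	32829
zs97_mtp_picked	4714
zs97_circularized	4415
zs97_anchored_contigs	318
zs97_gaps_filled	81
mh63_library_clones	36864
mh63_tagged_clones	30749
mh63_mtp_picked	4751
mh63_circularized	4320
mh63_anchored_contigs	216
mh63_gaps_filled	35
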