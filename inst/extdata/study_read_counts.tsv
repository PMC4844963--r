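sample_id	sequenced	genome_mapped	cluster_mapped
brain_10dpp	199003	161869	741
brain_14dpp	457461	390929	1106
brain_adult	529081	453456	31398
testes_10dpp	223341	213740	58835
testes_14dpp	1177846	1132436	340181
testes_adult	8359064	8302184	8234258
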