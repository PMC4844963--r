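reference_sample	shared_unique	query_unique
testes_adult	13253	14978
testes_10dpp	2692	14978
testes_14dpp	6417	14978
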