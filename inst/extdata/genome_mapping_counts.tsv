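quantity	count
clean_redundant	16675173
clean_unique	3328500
mapped_redundant	12521493
mapped_unique	2440952
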