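quantity	count
known_mirnas	557
known_mirnas_with_targets	349
known_targets_total	3959
known_one_target_mirnas	74
mir4993_targets	707
novel_mirnas	275
novel_mirnas_with_targets	193
novel_targets_total	1614
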