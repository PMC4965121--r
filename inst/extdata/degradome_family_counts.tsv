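quantity	count
conserved_families	21
conserved_cleaved_targets	54
nonconserved_families	39
nonconserved_cleaved_targets	61
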