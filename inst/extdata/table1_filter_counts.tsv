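category	count
total_reads	17186803
high_quality	17103178
adaptor3_null	6753
insert_null	3712
adaptor5_contaminant	31246
shorter_than_18	386179
polyA	115
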