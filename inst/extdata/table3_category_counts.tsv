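category	unique_count	redundant_count
exon_antisense	81691	249923
exon_sense	146581	515834
intron_antisense	77675	264105
intron_sense	117152	572501
miRNA	39245	3654996
rRNA	85358	2342951
snRNA	2608	11118
snoRNA	858	3394
tRNA	10042	737196
unannotated	2767290	8323155
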