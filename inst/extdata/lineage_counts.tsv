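genotype	functional_class	strain_class	snv	indel
MSH2-genomic	genomic-WT	wild_type	1	0
msh2-null	null	null_like	7	140
msh2-A618V	structural	null_like	8	109
msh2-R657G	structural	null_like	6	141
msh2-L183P	structural	null_like	7	143
msh2-C195Y	structural	null_like	15	158
msh2-C345F	structural	null_like	16	180
msh2-D621G	structural	null_like	12	144
msh2-P640T	structural	null_like	10	125
msh2-R542L	dna-binding	null_like	4	135
msh2-D524Y	dna-binding	null_like	14	151
msh2-G688D	atpase	null_like	15	139
msh2-G693R	atpase	null_like	9	146
msh2-S695P	atpase	null_like	14	159
msh2-S742F	atpase	null_like	9	156
msh2-T743K	atpase	null_like	5	147
msh2-G770R	atpase	null_like	7	147
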