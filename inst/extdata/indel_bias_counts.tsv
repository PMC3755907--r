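motif_class	n_ins	n_del
A/T	151	1983
C/G	10	28
AT/TA	71	42
GT/CA	6	11
GA/CT	1	1
AAT/TTA	1	1
AAC/TTG	1	3
ATT/TAA	3	0
ACG/TGC	0	1
ATG/TAC	3	1
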