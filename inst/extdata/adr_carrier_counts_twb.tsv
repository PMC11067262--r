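allele	carriers	cohort_size	allele_freq
C*01:02	21317	59448	0.1991
C*03:02	12469	59448	0.1114
B*58:01	12427	59448	0.1110
B*13:01	7133	59448	0.0618
DPB1*03:01	5502	59448	0.0474
B*15:02	4984	59448	0.0428
B*35:01	3305	59448	0.0282
A*31:01	2449	59448	0.0208
B*15:11	944	59448	0.0080
DRB1*01:01	615	59448	0.0052
B*57:01	203	59448	0.0017
B*59:01	0	59448	0.0000
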