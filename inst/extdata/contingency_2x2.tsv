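table	row	a	b	c	d
1	twins	2	36	4	58
3	hie	8	30	15	47
4	perinatal_death	1	37	0	62
4	rds	3	35	4	58
5	maternal_complications	1	37	13	49
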