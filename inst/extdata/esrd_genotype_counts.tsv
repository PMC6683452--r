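snp	hom_ref_genotype	het_genotype	hom_alt_genotype	control_hom_ref	control_het	control_hom_alt	case_hom_ref	case_het	case_hom_alt
rs11826681	CC	CG	GG	304	421	122	288	418	141
rs17036427	GG	GC	CC	723	119	5	718	122	7
rs59118205	CC	TC	TT	745	98	4	753	92	2
rs7284245	GG	GT	TT	611	211	23	582	247	18
rs7651075	GG	AG	AA	219	398	230	185	440	222
rs77836284	CC	TC	TT	703	133	11	709	130	8
rs78229468	AA	GA	GG	697	146	4	696	143	8
rs79143300	GG	GT	TT	737	105	5	731	113	3
rs9395890	GG	GT	TT	153	419	274	138	379	324
rs9925427	AA	GA	GG	638	208	1	665	192	0
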