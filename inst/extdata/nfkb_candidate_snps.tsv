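chrom	pos	id	call_rate	maf	ref	alt	context
1	11229433	rs17036427	1.000	0.0807	G	C	AAAGGCAGG[G/C]ATTTTCCCC
1	19372561	rs79143300	0.997	0.0820	G	T	CAATGTGGC[G/T]GGAATTTCC
2	203037846	rs76552560	0.995	0.1346	G	A	AAGTCCCCC[G/A]GGAAGTCCC
3	14693650	rs7651075	0.997	0.4940	G	A	CCGTGGGTT[G/A]GGAAACTCC
6	44032378	rs59118205	0.997	0.0594	C	T	GGGGTTTCC[C/T]CACCATGAT
6	53820994	rs9395890	0.999	0.4157	T	G	GTGACAGCT[T/G]GGAAGTCCC
11	30344883	rs11826681	0.916	0.4157	C	G	CGTGAGGGG[C/G]ATTTCCAGC
11	85506994	rs11234413	1.000	0.0973	G	A	CATCACCAG[G/A]GGAATCTCC
11	94465585	rs2851583	0.999	0.0572	A	G	TTCTGAAGG[A/G]AAGTCCCTC
16	1275896	rs9925427	0.993	0.1258	A	G	GCAGCGCCC[A/G]GGACTTTCC
16	81444782	rs78229468	0.955	0.0861	A	G	TGCTGCTGG[A/G]AAGTTCCTG
16	86553836	rs77836284	0.999	0.0858	C	T	GGGGATTTC[C/T]CGCTCGGCT
17	34219824	rs3826454	0.998	0.1050	A	T	CCCTTGGGG[A/T]ATTTCCTCA
19	54398240	rs67087171	1.000	0.1153	G	A	TAGAAGGGC[G/A]GGATTTCCC
22	29613441	rs7284245	0.997	0.1650	G	T	CTTGGGCCG[G/T]GGACTTCCC
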