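snp	chrom	pos	parentA	parentB	F1	NIL_BB	NIL_HH
ex001	1	1500000	A/A	G/G	A/G	A/A	A/A
ex002	1	2800000	T/T	T/T	T/T	T/T	T/T
ex003	1	4100000	C/C	A/A	A/C	C/C	A/A
ex004	1	5600000	G/G	G/G	G/G	G/G	G/G
ex005	2	900000	A/A	T/T	A/T	A/A	T/T
ex006	2	2200000	G/G	C/C	C/G	G/G	C/C
ex007	2	3700000	T/T	C/C	C/T	T/T	C/C
ex008	2	5100000	A/A	A/A	A/A	-/-	A/A
ex009	3	1300000	C/C	G/G	C/G	C/C	G/G
ex010	3	2600000	A/A	G/G	A/G	A/A	G/G
ex011	3	4000000	T/T	A/A	A/T	T/T	A/A
ex012	UNKNOWN		A/A	C/C	A/C	A/A	C/C
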