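##fileformat=VCFv4.2
##source=genofp synthetic toy genome (simulated; not a real individual)
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	TOY
1	4532	.	T	G	.	PASS	.	GT	0/1
1	6544	.	G	A	.	PASS	.	GT	0/1
1	7276	.	C	T	.	PASS	.	GT	0/1
1	9003	.	A	C	.	PASS	.	GT	0/1
1	13178	.	C	T	.	PASS	.	GT	0/1
1	13286	.	G	C	.	PASS	.	GT	0/1
1	13801	.	T	C	.	PASS	.	GT	0/1
1	14003	.	A	C	.	PASS	.	GT	0/1
1	14946	.	A	C	.	PASS	.	GT	0/1
1	17527	.	G	C	.	PASS	.	GT	0/1
1	17944	.	G	T	.	PASS	.	GT	0/1
1	19010	.	C	A	.	PASS	.	GT	0/1
1	19122	.	G	A	.	PASS	.	GT	0/1
2	72	.	A	G	.	PASS	.	GT	0/1
2	126	.	A	G	.	PASS	.	GT	0/1
2	1443	.	G	A	.	PASS	.	GT	0/1
2	1497	.	G	T	.	PASS	.	GT	0/1
2	1520	.	G	A	.	PASS	.	GT	0/1
2	4011	.	C	G	.	PASS	.	GT	0/1
2	4176	.	C	T	.	PASS	.	GT	0/1
2	4665	.	C	T	.	PASS	.	GT	0/1
2	6441	.	C	T	.	PASS	.	GT	0/1
2	6927	.	T	A	.	PASS	.	GT	0/1
2	8083	.	T	A	.	PASS	.	GT	0/1
2	8916	.	G	A	.	PASS	.	GT	0/1
2	9342	.	C	T	.	PASS	.	GT	0/1
2	10473	.	T	C	.	PASS	.	GT	0/1
2	11095	.	G	C	.	PASS	.	GT	0/1
2	11840	.	C	T	.	PASS	.	GT	0/1
2	11923	.	T	G	.	PASS	.	GT	0/1
2	13272	.	T	C	.	PASS	.	GT	0/1
2	14287	.	A	G	.	PASS	.	GT	0/1
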