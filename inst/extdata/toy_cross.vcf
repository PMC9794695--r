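##fileformat=VCFv4.2
##source=clonescan synthetic toy fixture: 10 candidate sites, two parents x2 replicates, F1 x2 replicates
##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	P1_1	P1_2	P2_1	P2_2	F1_1	F1_2
chr1	100	.	A	G	.	PASS	.	AD	10,0	8,0	0,12	0,9	5,5	6,6
chr1	200	.	C	T	.	PASS	.	AD	0,11	0,9	10,0	12,0	6,5	7,7
chr1	300	.	G	A	.	PASS	.	AD	9,0	10,0	0,8	0,10	2,6	5,5
chr1	400	.	T	C	.	PASS	.	AD	10,0	9,0	0,10	0,9	7,3	5,6
chr1	500	.	A	C	.	PASS	.	AD	10,0	3,0	0,9	0,11	5,5	4,6
chr1	600	.	G	T	.	PASS	.	AD	9,0	8,0	10,0	12,0	5,4	6,6
chr1	700	.	C	G	.	PASS	.	AD	10,0	0,9	0,8	0,10	5,5	6,5
chr1	800	.	A	T	.	PASS	.	AD	10,0	9,0	0,8	0,11	10,0	5,5
chr1	900	.	T	G	.	PASS	.	AD	11,0	9,0	0,10	0,0	6,6	5,7
chr1	1000	.	C	A	.	PASS	.	AD	8,2	9,0	0,9	0,12	5,5	6,4
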