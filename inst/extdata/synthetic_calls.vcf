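##fileformat=VCFv4.2
##contig=<ID=chr1,length=300>
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO
chr1	244	.	C	A	.	PASS	.
chr1	259	.	A	T	.	PASS	.
chr1	185	.	C	A	.	PASS	.
chr1	288	.	A	T	.	PASS	.
chr1	198	.	A	T	.	PASS	.
chr1	143	.	C	A	.	PASS	.
chr1	70	.	G	GA	.	PASS	.
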