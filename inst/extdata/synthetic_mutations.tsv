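sample	chrom	pos	ref	alt	ccf	strand
T1	chr1	244	C	A	1	NA
T1	chr1	259	A	T	1	NA
T1	chr1	185	C	A	1	coding
T1	chr1	288	A	T	1	NA
T1	chr1	198	A	T	1	NA
T1	chr1	143	C	A	0.987	noncoding
T1	chr1	193	C	G	0.993	coding
T1	chr1	235	G	A	0.451	noncoding
T1	chr1	48	C	T	0.715	NA
T1	chr1	194	T	A	0.317	NA
T1	chr1	50	A	G	0.834	coding
T1	chr1	23	A	G	0.434	coding
T1	chr2	149	G	C	0.996	noncoding
T1	chr2	163	T	G	0.806	NA
T1	chr2	88	A	T	0.486	noncoding
T1	chr2	58	G	T	0.539	coding
T1	chr2	199	C	G	0.341	noncoding
T1	chr2	138	T	C	0.052	NA
T1	chr2	28	C	A	0.459	coding
T1	chr2	175	A	T	0.498	NA
T2	chr1	85	A	T	0.283	noncoding
T2	chr1	158	G	T	0.776	NA
T2	chr1	239	C	G	0.304	noncoding
T2	chr1	197	A	C	0.516	NA
T2	chr1	169	C	T	0.478	coding
T2	chr1	88	A	G	0.769	coding
T2	chr1	219	A	G	0.164	NA
T2	chr1	203	A	C	0.442	noncoding
T2	chr1	111	T	G	0.523	NA
T2	chr1	120	C	A	0.477	noncoding
T2	chr1	50	C	A	0.5	NA
T2	chr1	60	AT	A	0.5	NA
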