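locus	chrom	pos	HeLa	fibroblast	iPS_p31	iPS_p41
1p35.1	chr1	32614846	0	1	1	1
10q24.2	chr10	99256369	0	1	1	1
12q12	chr12	43919854	0	1	1	1
13q31.3	chr13	90090934	0	1	1	1
2q22.3	chr2	147700152	0	0	1	1
11q13.3	chr11	70471356	0	0	1	1
15q14	chr15	36348199	0	0	1	1
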