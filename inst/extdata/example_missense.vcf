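##fileformat=VCFv4.2
##INFO=<ID=MC,Number=1,Type=String,Description="MC">
##INFO=<ID=AA,Number=1,Type=String,Description="AA">
##INFO=<ID=GENE,Number=1,Type=String,Description="GENE">
##INFO=<ID=AF,Number=1,Type=String,Description="AF">
##INFO=<ID=DP,Number=1,Type=String,Description="DP">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO
21	48679036	.	T	C	.	PASS	MC=missense_variant;AA=S/N;GENE=GENE1375;AF=0;DP=59
18	48582928	.	T	A	.	PASS	MC=missense_variant;AA=S/Y;GENE=GENE1505;AF=0;DP=18
18	19237271	.	G	A	.	PASS	MC=synonymous_variant;AA=F/S;GENE=GENE802;AF=0;DP=35
22	44021861	.	C	G	.	PASS	MC=missense_variant;AA=G/P;GENE=GENE1880;AF=0;DP=51
4	17580626	.	G	T	.	PASS	MC=missense_variant;AA=L/S;GENE=GENE379;AF=0.00057;DP=57
1	25860246	.	T	G	.	PASS	MC=missense_variant;AA=N/C;GENE=GENE1212;AF=0.00592;DP=67
20	18429701	.	G	T	.	PASS	MC=synonymous_variant;AA=D/N;GENE=GENE1736;AF=1e-05;DP=64
14	7873302	.	C	G	.	PASS	MC=missense_variant;AA=I/L;GENE=GENE421;AF=1e-05;DP=79
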