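##gff-version 3
SPA1	clonetrace	gene	12000	12900	.	+	.	ID=gene01
SPA1	clonetrace	mRNA	12000	12900	.	+	.	ID=mrna01;Parent=gene01
SPA1	clonetrace	exon	12000	12300	.	+	.	Parent=mrna01
SPA1	clonetrace	exon	12600	12900	.	+	.	Parent=mrna01
SPA1	clonetrace	CDS	12100	12300	.	+	0	Parent=mrna01
SPA1	clonetrace	CDS	12600	12800	.	+	0	Parent=mrna01
SPE2	clonetrace	gene	30000	31500	.	-	.	ID=gene02
SPE2	clonetrace	mRNA	30000	31500	.	-	.	ID=mrna02;Parent=gene02
SPE2	clonetrace	exon	30000	30600	.	-	.	Parent=mrna02
SPE2	clonetrace	exon	31000	31500	.	-	.	Parent=mrna02
SPE2	clonetrace	CDS	30100	30600	.	-	0	Parent=mrna02
SPE2	clonetrace	CDS	31000	31498	.	-	0	Parent=mrna02
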