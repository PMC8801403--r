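##gff-version 3
# toy two-transcript annotation; intervals are hand-counted in the tests
chr1	toy	gene	101	1500	.	+	.	ID=g1;gene_id=g1
chr1	toy	transcript	101	1500	.	+	.	ID=t1;Parent=g1;transcript_id=t1;gene_id=g1;transcript_type=protein_coding
chr1	toy	exon	101	400	.	+	.	Parent=t1;transcript_id=t1;gene_id=g1;transcript_type=protein_coding
chr1	toy	exon	501	700	.	+	.	Parent=t1;transcript_id=t1;gene_id=g1;transcript_type=protein_coding
chr1	toy	exon	801	1500	.	+	.	Parent=t1;transcript_id=t1;gene_id=g1;transcript_type=protein_coding
chr1	toy	CDS	251	400	.	+	0	Parent=t1;transcript_id=t1;gene_id=g1;transcript_type=protein_coding
chr1	toy	CDS	501	700	.	+	0	Parent=t1;transcript_id=t1;gene_id=g1;transcript_type=protein_coding
chr2	toy	gene	1001	3000	.	-	.	ID=g2;gene_id=g2
chr2	toy	transcript	1001	3000	.	-	.	ID=t2;Parent=g2;transcript_id=t2;gene_id=g2;transcript_type=protein_coding
chr2	toy	exon	1001	1800	.	-	.	Parent=t2;transcript_id=t2;gene_id=g2;transcript_type=protein_coding
chr2	toy	exon	2001	2650	.	-	.	Parent=t2;transcript_id=t2;gene_id=g2;transcript_type=protein_coding
chr2	toy	exon	2901	3000	.	-	.	Parent=t2;transcript_id=t2;gene_id=g2;transcript_type=protein_coding
chr2	toy	CDS	1101	1800	.	-	0	Parent=t2;transcript_id=t2;gene_id=g2;transcript_type=protein_coding
chr2	toy	CDS	2001	2550	.	-	0	Parent=t2;transcript_id=t2;gene_id=g2;transcript_type=protein_coding
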