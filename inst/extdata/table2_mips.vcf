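##fileformat=VCFv4.2
##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">
##INFO=<ID=TX,Number=1,Type=String,Description="Transcript accession">
##INFO=<ID=CDNA,Number=1,Type=String,Description="HGVS cDNA change">
##INFO=<ID=PROT,Number=1,Type=String,Description="HGVS protein change">
##INFO=<ID=CSQ_CLASS,Number=1,Type=String,Description="Consequence class">
##INFO=<ID=PP_CAT,Number=1,Type=String,Description="PolyPhen-2 category">
##INFO=<ID=PP_SCORE,Number=1,Type=Float,Description="PolyPhen-2 score">
##INFO=<ID=AF_EVS,Number=1,Type=Float,Description="EVS allele frequency">
##INFO=<ID=AF_GNOMAD,Number=1,Type=Float,Description="GNOMAD allele frequency">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">
##FORMAT=<ID=ADF,Number=R,Type=Integer,Description="Forward-strand allelic depths">
##FORMAT=<ID=ADR,Number=R,Type=Integer,Description="Reverse-strand allelic depths">
##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	10179	10194	10278	10190	10322	20871	20785
15	59464211	.	T	C	.	PASS	GENE=MYO1E;TX=NM_004998.3;CDNA=c.A44G;PROT=p.(Asn15Ser);CSQ_CLASS=missense;PP_CAT=probably_damaging;PP_SCORE=0.901;AF_EVS=0;AF_GNOMAD=0.00002031	GT:GQ:ADF:ADR:DP	0/0:99:15,0:15,0:30	0/0:99:15,0:14,0:29	0/0:99:15,0:15,0:30	0/0:99:16,0:14,0:30	0/1:99:9,8:9,8:34	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30
15	59464231	.	T	C	.	PASS	GENE=MYO1E;TX=NM_004998.3;CDNA=c.A49G;PROT=p.(Lys17Glu);CSQ_CLASS=missense;PP_CAT=probably_damaging;PP_SCORE=0.85;AF_EVS=0;AF_GNOMAD=0.00001625	GT:GQ:ADF:ADR:DP	0/0:99:15,0:15,0:30	0/0:99:15,0:14,0:29	0/0:99:15,0:15,0:30	0/1:99:8,8:9,8:33	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30
15	59500000	.	G	A	.	PASS	GENE=MYO1E;TX=NM_004998.3;CDNA=c.1400G>A;PROT=p.(Arg467His);CSQ_CLASS=missense;PP_CAT=probably_damaging;PP_SCORE=0.99;AF_GNOMAD=0.035	GT:GQ:ADF:ADR:DP	0/1:99:9,8:9,8:34	0/0:99:15,0:14,0:29	0/0:99:15,0:15,0:30	0/0:99:16,0:14,0:30	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30
15	59501000	.	C	T	.	PASS	GENE=MYO1E;TX=NM_004998.3;CDNA=c.1350C>T;PROT=p.(Thr450Met);CSQ_CLASS=missense;PP_CAT=benign;PP_SCORE=0.21	GT:GQ:ADF:ADR:DP	0/0:99:15,0:15,0:30	0/0:99:15,0:14,0:29	0/0:99:15,0:15,0:30	0/0:99:16,0:14,0:30	0/0:99:15,0:15,0:30	0/1:99:9,8:9,8:34	0/0:99:15,0:15,0:30
15	59519705	.	C	A	.	PASS	GENE=MYO1E;TX=NM_004998.3;CDNA=c.G595T;PROT=p.(Val199Leu);CSQ_CLASS=missense;PP_CAT=probably_damaging;PP_SCORE=0.848;AF_EVS=0;AF_GNOMAD=0.000008122	GT:GQ:ADF:ADR:DP	0/0:99:15,0:15,0:30	0/0:99:15,0:14,0:29	0/0:99:15,0:15,0:30	0/0:99:16,0:14,0:30	0/0:99:15,0:15,0:30	0/1:99:9,8:9,8:34	0/0:99:15,0:15,0:30
15	59519746	.	T	C	.	PASS	GENE=MYO1E;TX=NM_004998.3;CDNA=c.A554G;PROT=p.(Asp185Gly);CSQ_CLASS=missense;PP_CAT=probably_damaging;PP_SCORE=0.866;AF_EVS=0.001157407;AF_GNOMAD=0.002103	GT:GQ:ADF:ADR:DP	0/0:99:15,0:15,0:30	0/0:99:15,0:14,0:29	0/1:99:9,8:9,8:34	0/0:99:16,0:14,0:30	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30	0/1:99:8,9:9,8:34
15	59564603	.	C	T	.	PASS	GENE=MYO1E;TX=NM_004998.3;CDNA=c.G2345A;PROT=p.(Arg782Gln);CSQ_CLASS=missense;PP_CAT=probably_damaging;PP_SCORE=0.93	GT:GQ:ADF:ADR:DP	0/0:99:15,0:15,0:30	0/1:99:9,8:9,8:34	0/0:99:15,0:15,0:30	0/0:99:16,0:14,0:30	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30
15	59564608	.	T	C	.	PASS	GENE=MYO1E;TX=NM_004998.3;CDNA=c.A2365G;PROT=p.(Lys789Glu);CSQ_CLASS=missense;PP_CAT=probably_damaging;PP_SCORE=0.925;AF_EVS=0;AF_GNOMAD=0.0000184	GT:GQ:ADF:ADR:DP	0/1:99:9,8:9,8:34	0/0:99:15,0:14,0:29	0/0:99:15,0:15,0:30	0/0:99:16,0:14,0:30	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30
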