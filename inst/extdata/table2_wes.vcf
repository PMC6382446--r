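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
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	201	265	553	28	552	389	574
15	59453352	.	G	C	.	PASS	GENE=MYO1E;TX=NM_004998.3;CDNA=c.2705G>C;PROT=p.(Gly902Ala);CSQ_CLASS=missense;PP_CAT=probably_damaging;PP_SCORE=0.993	GT:GQ:ADF:ADR:DP	0/0:99:15,0:15,0:30	0/0:99:15,0:14,0:29	0/0:99:15,0:15,0:30	0/0:99:16,0:14,0:30	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30	0/1:99:9,8:10,7:34
15	59464193	.	G	A	.	PASS	GENE=MYO1E;TX=NM_004998.3;CDNA=c.2383G>A;PROT=p.(Gly795Arg);CSQ_CLASS=missense;PP_CAT=probably_damaging;PP_SCORE=0.997;AF_EVS=0.000077;AF_GNOMAD=0.0005989	GT:GQ:ADF:ADR:DP	0/0:99:15,0:15,0:30	0/0:99:15,0:14,0:29	0/0:99:15,0:15,0:30	0/0:99:16,0:14,0:30	0/0:99:15,0:15,0:30	0/1:99:8,9:9,8:34	0/0:99:15,0:15,0:30
15	59497622	.	C	G	.	PASS	GENE=MYO1E;TX=NM_004998.3;CDNA=c.1593C>G;PROT=p.(Ile531Met);CSQ_CLASS=missense;PP_CAT=probably_damaging;PP_SCORE=0.988;AF_EVS=0.006480;AF_GNOMAD=0.007179	GT:GQ:ADF:ADR:DP	0/0:99:15,0:15,0:30	0/0:99:15,0:14,0:29	0/0:99:15,0:15,0:30	0/1:99:9,8:8,8:33	0/1:99:8,8:9,8:33	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30
15	59506892	.	C	G	.	PASS	GENE=MYO1E;TX=NM_004998.3;CDNA=c.1135C>G;PROT=p.(His379Asp);CSQ_CLASS=missense;PP_CAT=probably_damaging;PP_SCORE=0.982;AF_EVS=0.001543;AF_GNOMAD=0.001320	GT:GQ:ADF:ADR:DP	0/0:99:15,0:15,0:30	0/1:99:9,8:9,7:33	0/1:99:8,9:9,8:34	0/0:99:16,0:14,0:30	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30
15	59519746	.	A	G	.	PASS	GENE=MYO1E;TX=NM_004998.3;CDNA=c.554A>G;PROT=p.(Asp185Gly);CSQ_CLASS=missense;PP_CAT=probably_damaging;PP_SCORE=0.99;AF_EVS=0.001157;AF_GNOMAD=0.002103	GT:GQ:ADF:ADR:DP	0/1:99:9,8:9,8:34	0/0:99:15,0:14,0:29	0/0:99:15,0:15,0:30	0/0:99:16,0:14,0:30	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30
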