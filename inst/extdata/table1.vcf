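##fileformat=VCFv4.2
##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">
##INFO=<ID=TX,Number=1,Type=String,Description="Transcript accession">
##INFO=<ID=CDNA,Number=1,Type=String,Description="HGVS cDNA change">
##INFO=<ID=PROT,Number=1,Type=String,Description="HGVS protein change">
##INFO=<ID=CSQ_CLASS,Number=1,Type=String,Description="Consequence class">
##INFO=<ID=PP_CAT,Number=1,Type=String,Description="PolyPhen-2 category">
##INFO=<ID=PP_SCORE,Number=1,Type=Float,Description="PolyPhen-2 score">
##INFO=<ID=AF_GNOMAD,Number=1,Type=Float,Description="GNOMAD allele frequency">
##INFO=<ID=AF_EXAC,Number=1,Type=Float,Description="EXAC allele frequency">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">
##FORMAT=<ID=ADF,Number=R,Type=Integer,Description="Forward-strand allelic depths">
##FORMAT=<ID=ADR,Number=R,Type=Integer,Description="Reverse-strand allelic depths">
##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	224_FA	224_MO	224_A1	224_A2	3646_FA	3646_MO	3646_A1	3646_B1	3646_C1	25_FA	25_MO	25_P	260_FA	260_MO	260_P	270_FA	270_MO	270_A1	270_A2	270_A3
1	11851333	.	G	A	.	PASS	GENE=MTHFR;TX=NM_005957.4;CDNA=c.1683G>A;PROT=p.(Trp561Ter);CSQ_CLASS=stop_gained	GT:GQ:ADF:ADR:DP	0/0:99:16,0:15,0:31	0/1:99:9,8:10,7:34	0/1:99:8,9:9,8:34	0/1:99:10,7:8,9:34	0/0:99:15,0:14,0:29	0/0:99:14,0:16,0:30	0/0:99:17,0:13,0:30	0/0:99:15,0:15,0:30	0/0:99:16,0:14,0:30	0/0:99:15,0:15,0:30	0/0:99:14,0:15,0:29	0/0:99:16,0:16,0:32	0/0:99:15,0:14,0:29	0/0:99:15,0:15,0:30	0/0:99:14,0:16,0:30	0/0:99:15,0:15,0:30	0/0:99:16,0:14,0:30	0/0:99:15,0:15,0:30	0/0:99:14,0:15,0:29	0/0:99:15,0:16,0:31
1	116185000	.	C	T	.	PASS	GENE=VANGL1;TX=NM_138959.3;CDNA=c.346C>T;PROT=p.(Arg116Trp);CSQ_CLASS=missense;PP_CAT=probably_damaging;PP_SCORE=0.95;AF_GNOMAD=0.02;AF_EXAC=0.018	GT:GQ:ADF:ADR:DP	0/0:99:15,0:15,0:30	0/0:99:14,0:15,0:29	0/0:99:15,0:15,0:30	0/0:99:16,0:14,0:30	0/0:99:15,0:15,0:30	0/0:99:15,0:14,0:29	0/0:99:15,0:15,0:30	0/0:99:14,0:16,0:30	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30	0/0:99:16,0:14,0:30	0/1:99:8,7:9,8:32	0/0:99:15,0:15,0:30	0/0:99:14,0:15,0:29	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30	0/0:99:15,0:14,0:29	0/0:99:16,0:15,0:31	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30
2	179400000	.	C	T	.	PASS	GENE=TTN;TX=NM_001267550.2;CDNA=c.10000C>T;PROT=p.(Gln3334Ter);CSQ_CLASS=stop_gained	GT:GQ:ADF:ADR:DP	0/0:99:15,0:15,0:30	0/0:99:15,0:14,0:29	0/0:99:15,0:15,0:30	0/1:99:9,8:8,7:32	0/0:99:15,0:15,0:30	0/0:99:14,0:15,0:29	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30	0/0:99:16,0:14,0:30	0/0:99:15,0:15,0:30	0/0:99:15,0:14,0:29	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30	0/0:99:14,0:15,0:29	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30	0/0:99:15,0:14,0:29	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30
2	223084000	.	G	A	.	PASS	GENE=PAX3;TX=NM_181457.4;CDNA=c.300G>A;PROT=p.(=);CSQ_CLASS=synonymous	GT:GQ:ADF:ADR:DP	0/0:99:15,0:15,0:30	0/0:99:15,0:14,0:29	0/1:99:8,8:9,7:32	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30	0/0:99:14,0:15,0:29	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30	0/0:99:16,0:14,0:30	0/0:99:15,0:15,0:30	0/0:99:15,0:14,0:29	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30	0/0:99:14,0:15,0:29	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30	0/0:99:15,0:14,0:29	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30
4	77356253	.	C	T	.	PASS	GENE=SHROOM3;TX=NM_020859.4;CDNA=c.280C>T;PROT=p.(Arg94Ter);CSQ_CLASS=stop_gained	GT:GQ:ADF:ADR:DP	0/0:99:15,0:15,0:30	0/0:99:15,0:14,0:29	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30	0/0:99:14,0:15,0:29	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30	0/0:99:16,0:14,0:30	0/0:99:15,0:15,0:30	0/0:99:15,0:14,0:29	0/1:99:9,7:8,8:32	0/0:99:15,0:15,0:30	0/0:99:14,0:15,0:29	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30	0/0:99:15,0:14,0:29	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30
8	12957469	.	C	T	.	PASS	GENE=DLC1;TX=NM_006094.4;CDNA=c.1066C>T;PROT=p.(Gln356Ter);CSQ_CLASS=stop_gained	GT:GQ:ADF:ADR:DP	0/0:99:15,0:15,0:30	0/0:99:15,0:14,0:29	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30	0/0:99:14,0:15,0:29	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30	0/0:99:16,0:14,0:30	0/0:99:15,0:15,0:30	0/1:99:8,8:9,8:33	0/1:99:9,8:8,8:33	0/0:99:15,0:15,0:30	0/0:99:14,0:15,0:29	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30	0/0:99:15,0:14,0:29	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30
8	13357460	.	C	T	.	PASS	GENE=DLC1;TX=NM_006094.4;CDNA=c.121C>T;PROT=p.(Gln41Ter);CSQ_CLASS=stop_gained	GT:GQ:ADF:ADR:DP	0/0:99:15,0:15,0:30	0/0:99:15,0:14,0:29	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30	0/1:99:9,8:9,7:33	0/1:99:8,9:9,8:34	0/1:99:10,7:9,8:34	0/1:99:9,8:8,9:34	0/0:99:15,0:15,0:30	0/0:99:15,0:14,0:29	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30	0/0:99:14,0:15,0:29	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30	0/0:99:15,0:14,0:29	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30
8	143790000	.	C	T	.	PASS	GENE=SCRIB;TX=NM_182706.5;CDNA=c.2000C>T;PROT=p.(Ala667Val);CSQ_CLASS=missense;PP_CAT=benign;PP_SCORE=0.12	GT:GQ:ADF:ADR:DP	0/0:99:15,0:15,0:30	0/0:99:15,0:14,0:29	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30	0/0:99:14,0:15,0:29	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30	0/0:99:16,0:14,0:30	0/0:99:15,0:15,0:30	0/0:99:15,0:14,0:29	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30	0/0:99:14,0:15,0:29	0/1:99:8,8:9,7:32	0/0:99:15,0:15,0:30	0/0:99:15,0:14,0:29	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30
10	33197323	.	A	AA	.	PASS	GENE=ITGB1;TX=NM_133376.2;CDNA=c.2303_2304insA;PROT=p.(Lys768fs);CSQ_CLASS=frameshift	GT:GQ:ADF:ADR:DP	0/0:99:15,0:15,0:30	0/0:99:15,0:14,0:29	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30	0/0:99:14,0:15,0:29	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30	0/0:99:16,0:14,0:30	0/0:99:15,0:15,0:30	0/0:99:15,0:14,0:29	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30	0/1:99:9,7:9,8:33	0/1:99:8,8:9,8:33	0/0:99:15,0:15,0:30	0/0:99:15,0:14,0:29	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30
12	99042236	.	A	AT	.	PASS	GENE=APAF1;TX=NM_181868.1;CDNA=c.99_100insT;PROT=p.(Gly33fs);CSQ_CLASS=frameshift	GT:GQ:ADF:ADR:DP	0/0:99:15,0:15,0:30	0/0:99:15,0:14,0:29	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30	0/0:99:14,0:15,0:29	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30	0/0:99:16,0:14,0:30	0/0:99:15,0:15,0:30	0/0:99:15,0:14,0:29	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30	0/0:99:14,0:15,0:29	0/0:99:15,0:15,0:30	./.:.:.,.:.,.:.	0/0:99:15,0:14,0:29	0/1:99:9,8:9,8:34	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30
22	46360000	.	G	A	.	PASS	GENE=CELSR1;TX=NM_014246.2;CDNA=c.5000G>A;PROT=p.(Arg1667His);CSQ_CLASS=missense;PP_CAT=probably_damaging;PP_SCORE=0.97	GT:GQ:ADF:ADR:DP	0/0:99:15,0:15,0:30	0/0:99:15,0:14,0:29	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30	0/0:99:14,0:15,0:29	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30	0/0:99:16,0:14,0:30	0/0:99:15,0:15,0:30	0/0:99:15,0:14,0:29	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30	0/0:99:14,0:15,0:29	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30	0/0:99:15,0:14,0:29	0/1:87:9,8:9,8:34	0/0:99:15,0:15,0:30	0/0:99:15,0:15,0:30
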