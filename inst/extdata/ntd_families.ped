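224_414	224_FA	0	0	1	1	.
224_414	224_MO	0	0	2	1	.
224_414	224_A1	224_FA	224_MO	1	2	MMC
224_414	224_A2	224_FA	224_MO	1	2	MMC
3646	3646_FA	0	0	1	1	.
3646	3646_MO	0	0	2	2	MC
3646	3646_A1	3646_FA	3646_MO	2	2	MMC
3646	3646_B1	3646_FA	3646_MO	1	1	.
3646	3646_C1	0	0	2	2	MC
25	25_FA	0	0	1	1	.
25	25_MO	0	0	2	1	.
25	25_P	25_FA	25_MO	1	2	MMC
260	260_FA	0	0	1	1	.
260	260_MO	0	0	2	1	.
260	260_P	260_FA	260_MO	1	2	MMC
270	270_FA	0	0	1	1	.
270	270_MO	0	0	2	1	.
270	270_A1	270_FA	270_MO	1	2	MMC
270	270_A2	270_FA	270_MO	1	2	MMC
270	270_A3	270_FA	270_MO	2	2	MMC
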