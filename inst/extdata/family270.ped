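270	270_FA	0	0	1	1	.
270	270_MO	0	0	2	1	.
270	270_A1	270_FA	270_MO	1	2	MMC
270	270_A2	270_FA	270_MO	1	2	MMC
270	270_A3	270_FA	270_MO	2	2	MMC
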