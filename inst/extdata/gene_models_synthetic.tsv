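symbol	transcript	coding_length
MTHFR	NM_005957.4	1971
DLC1	NM_006094.4	4570
ITGB1	NM_133376.2	2397
APAF1	NM_181868.1	3744
MYO1E	NM_004998.3	3327
DYSF	NM_003494.4	6243
SHROOM3	NM_020859.4	5991
TTN	NM_001267550.2	100272
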