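# Genes excluded from burden testing for recurrent misalignment artifacts
# (editable; one symbol per line)
MUC4
HLA-DRB1
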