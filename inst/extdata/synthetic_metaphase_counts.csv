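group_id,n_total,n_breaks,n_translocations
WT,2000,18,6
polq_ko,1850,30,8
xrcc4_ko,1400,120,40
xrcc4_polq_ko,900,200,12
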