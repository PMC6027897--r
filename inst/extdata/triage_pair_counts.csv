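pair,n_prehit,n_high_bg,n_low_dmso,n_manual_pass
1&3,44,30,3,5
1&2,42,12,5,12
2&3,76,64,3,5
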