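analyte,pb_mean,pb_sd,fu
SDZ,29.2,9.1,0.708
SMX,57.3,7.9,0.427
SDMX,94.1,3.1,0.059
TMP,51.2,9.7,0.489
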