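composition,method,cblm_uF_cm2,cblm_sd_uF_cm2,n
POPC,discharge,0.51,0.17,80
POPC,period_converter,0.51,0.16,58
POPS,discharge,0.41,0.14,76
POPS,period_converter,0.41,0.13,34
POPC:POPS,discharge,0.31,0.07,60
POPC:POPS,period_converter,0.34,0.17,25
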