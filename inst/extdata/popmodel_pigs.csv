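analyte,block,parameter,route,value
SDZ,fixed,cl,,0.12
SDZ,fixed,v1,,0.3
SDZ,fixed,q,,0.32
SDZ,fixed,v2,,0.29
SDZ,fixed,ka,oral,0.5
SDZ,fixed,ka,im,1.3
SDZ,fixed,f,oral,0.93
SDZ,fixed,f,im,0.99
SDZ,beta_bw,cl,,0.51
SDZ,beta_bw,v1,,1.1
SDZ,omega,ka,,0.52
SDZ,gamma,cl,,0.33
SDZ,gamma,v1,,0.12
SDZ,gamma,v2,,0.62
SDZ,resid,a,,0.32
SDZ,meta,bw_ref,,31.1
SDMX,fixed,cl,,0.015
SDMX,fixed,v1,,0.13
SDMX,fixed,q,,0.2
SDMX,fixed,v2,,0.16
SDMX,fixed,ka,oral,0.6
SDMX,fixed,f,oral,0.68
SDMX,omega,ka,,0.37
SDMX,gamma,cl,,0.18
SDMX,gamma,v1,,0.4
SDMX,gamma,v2,,0.34
SDMX,resid,a,,0.22
SDMX,meta,bw_ref,,31.1
SMX,fixed,cl,,0.21
SMX,fixed,v1,,0.48
SMX,fixed,q,,0.83
SMX,fixed,v2,,0.17
SMX,fixed,ka,oral,1.82
SMX,fixed,f,oral,0.64
SMX,gamma,v1,,0.09
SMX,gamma,v2,,0.4
SMX,resid,a,,0.18
SMX,meta,bw_ref,,31.1
TMP,fixed,cl,,0.48
TMP,fixed,v1,,0.92
TMP,fixed,q,,1.26
TMP,fixed,v2,,0.86
TMP,fixed,ka,oral,0.66
TMP,fixed,ka,im,1.14
TMP,fixed,f,oral,0.58
TMP,fixed,f,im,0.99
TMP,beta_bw,cl,,0.78
TMP,beta_bw,v1,,1.33
TMP,omega,ka,,0.63
TMP,gamma,cl,,0.34
TMP,gamma,v1,,0.44
TMP,gamma,v2,,0.42
TMP,resid,a,,0.4
TMP,meta,bw_ref,,31.1
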