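instrument,timepoint,experimental_mean,experimental_sd,control_mean,control_sd
fma_ue,pre,40.84,8.6,36.61,7.4
fma_ue,post,55.92,7.3,42.23,7.9
arat,pre,24.23,4.9,21.23,8.2
arat,post,37.46,9.1,25.50,6.7
bbt,pre,15.11,6.7,11.76,8.6
bbt,post,39.50,12.8,15.69,8.4
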