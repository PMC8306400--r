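temperature_C,rate_mM_d
4,-0.06
10,-0.64
15,-0.73
20,-1.91
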