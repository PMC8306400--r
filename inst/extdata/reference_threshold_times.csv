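metabolite,temperature_C,threshold_time_d,threshold_sd_d,p_value
ethanol,4,57,7,0.035
ethanol,10,12.01,0.01,0.043
ethanol,15,3.82,0.01,0.037
ethanol,20,1.98,0.02,0.006
formic,4,33,2,0.045
formic,10,9.97,0.01,0.021
formic,15,3.31,0.01,0.007
formic,20,1.78,0.01,0.008
acetic,4,44,5,0.027
acetic,10,9.97,0.01,0.008
acetic,15,3.00,0.03,0.023
acetic,20,1.49,0.02,0.002
lactic,4,63,12,0.035
lactic,10,12.01,0.01,0.043
lactic,15,3.31,0.01,0.037
lactic,20,1.78,0.01,0.006
succinic,4,,,
succinic,10,16.5,0.5,0.021
succinic,15,5.33,0.04,0.006
succinic,20,2.23,0.01,0.009
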