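metabolite,shift_ppm,protons,pattern,J_Hz,J2_Hz,calib,window_ppm
citric,2.55,2,d,15.7,,1.0,0.05
citric,2.67,2,d,15.7,,1.0,0.05
ethanol,1.18,3,t,7.1,,1.0,0.05
lactic,1.32,3,d,6.9,,1.0,0.05
acetic,1.92,3,s,,,1.0,0.05
succinic,2.40,4,s,,,1.0,0.05
butyric,0.89,3,t,7.4,,1.0,0.05
formic,8.45,1,s,,,1.0,0.05
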