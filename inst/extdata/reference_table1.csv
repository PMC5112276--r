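variable,period,control_mean,control_sd,drought_mean,drought_sd,printed_effect_pct,printed_p
VPD,day,8.7,0.43,17.1,0.38,96.9,0.023
T_air,day,25.4,0.03,26.7,0.18,5.0,0.147
T_leaf,day,24.6,0.18,24.7,0.24,0.5,0.876
T_soil,day,16.7,0.08,17.1,0.11,2.3,0.747
SMC,day,30.9,0.28,24.1,0.14,-21.9,0.008
A_N,day,4.84,0.08,3.19,0.06,-34.1,0.017
g_s,day,0.06,0.00,0.02,0.00,-64.9,0.017
E,day,0.65,0.01,0.38,0.01,-42.0,0.020
Delta13C_obs,day,24.90,0.16,17.05,0.17,-31.5,<0.001
SR,day,4.16,0.04,2.46,0.04,-40.8,0.003
delta13C_SR,day,-25.52,0.09,-24.37,0.10,-4.5,0.008
SR,night,4.25,0.05,2.16,0.06,-49.3,0.005
delta13C_SR,night,-25.97,0.07,-24.57,0.17,-5.4,0.013
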