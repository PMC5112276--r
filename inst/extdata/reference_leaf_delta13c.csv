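period,fraction,control_mean,control_se,drought_mean,drought_se,printed_p
drought,bulk,-29.00,0.23,-28.98,0.09,0.500
drought,ws,-28.63,0.25,-27.21,0.08,0.050
drought,nf,-28.04,0.23,-25.55,0.27,0.050
recovery,bulk,-29.17,0.25,-29.12,0.16,0.500
recovery,ws,-29.55,0.14,-28.81,0.20,0.050
recovery,nf,-29.12,0.02,-28.58,0.58,0.350
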