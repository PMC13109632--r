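task,variable,rel,con,spe
sinusoidal,gain,0.98,0.70,0.28
sinusoidal,sd_gain,0.96,0.57,0.38
sinusoidal,rmse,0.86,0.59,0.27
sinusoidal,sd_rmse,0.74,0.51,0.22
sinusoidal,sacc_freq,0.94,0.76,0.18
triangular,gain,0.97,0.68,0.29
triangular,sd_gain,0.93,0.58,0.35
triangular,rmse,0.90,0.62,0.28
triangular,sd_rmse,0.70,0.48,0.22
triangular,sacc_freq,0.92,0.75,0.17
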