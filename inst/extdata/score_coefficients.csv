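region,cause,sex,alpha,p,beta_chol,beta_sbp,beta_smoker
low,chd,male,-22.1,4.71,0.24,0.018,0.71
low,chd,female,-29.8,6.36,0.24,0.018,0.71
low,non_chd,male,-26.7,5.64,0.02,0.022,0.63
low,non_chd,female,-31.0,6.62,0.02,0.022,0.63
high,chd,male,-21.0,4.62,0.24,0.018,0.71
high,chd,female,-28.7,6.23,0.24,0.018,0.71
high,non_chd,male,-25.7,5.47,0.02,0.022,0.63
high,non_chd,female,-30.0,6.42,0.02,0.022,0.63
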