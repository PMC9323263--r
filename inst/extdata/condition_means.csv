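label,theta_mean_deg,phi_mean_deg,sigma_deg
6GC/0,14.5,253.6,12.1
6GC/1,76.0,273.1,8.3
6GC/5,47.2,291.5,6.8
6GC/8,80.8,190.0,10.3
8TT,30.0,80.8,4.5
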