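composition,mode,slope,N,Ubr_mean_V,Ubr_sd_V,tbr_mean_s,tbr_sd_s,Awat_frac_percent
POPS,voltage_controlled,48100,18,0.80,0.04,17.59e-6,0.86e-6,0.65
POPS,voltage_controlled,21600,14,0.72,0.06,33.15e-6,2.76e-6,0.35
POPS,voltage_controlled,16700,13,0.67,0.05,41.24e-6,3.34e-6,0.28
POPS,voltage_controlled,11500,12,0.66,0.09,58.66e-6,7.71e-6,0.20
POPS,voltage_controlled,7800,15,0.62,0.08,81.05e-6,10.92e-6,0.14
POPS,voltage_controlled,5500,13,0.59,0.05,108.78e-6,8.72e-6,0.11
POPS,voltage_controlled,4800,15,0.61,0.04,129.24e-6,7.86e-6,0.09
POPS,current_controlled,10e-6,5,0.33,0.04,0.61,0.26,18.91e-6
POPS,current_controlled,8e-6,5,0.37,0.04,0.98,0.08,11.72e-6
POPS,current_controlled,4e-6,6,0.45,0.14,2.37,0.71,4.84e-6
POPS,current_controlled,1e-6,5,0.33,0.04,6.99,0.91,1.64e-6
POPS,current_controlled,0.5e-6,6,0.43,0.14,17.98,5.85,0.64e-6
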