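composition,mode,slope,N,Ubr_mean_V,Ubr_sd_V,tbr_mean_s,tbr_sd_s,Awat_frac_percent
POPC,voltage_controlled,48100,16,0.76,0.05,16.76e-6,1.14e-6,1.72
POPC,voltage_controlled,21600,17,0.67,0.05,30.50e-6,2.60e-6,0.95
POPC,voltage_controlled,16700,12,0.65,0.06,39.38e-6,3.87e-6,0.73
POPC,voltage_controlled,11500,12,0.59,0.05,52.25e-6,4.65e-6,0.55
POPC,voltage_controlled,7800,16,0.54,0.04,70.74e-6,5.07e-6,0.41
POPC,voltage_controlled,5500,16,0.54,0.05,99.24e-6,9.93e-6,0.29
POPC,voltage_controlled,4800,17,0.54,0.04,112.92e-6,8.32e-6,0.27
POPC,current_controlled,10e-6,8,0.25,0.14,0.64,0.55,45.20e-6
POPC,current_controlled,8e-6,9,0.12,0.16,1.22,1.16,23.63e-6
POPC,current_controlled,4e-6,7,0.32,0.16,1.63,1.35,17.76e-6
POPC,current_controlled,1e-6,11,0.11,0.11,3.30,0.98,8.74e-6
POPC,current_controlled,0.5e-6,16,0.26,0.13,5.97,2.09,4.83e-6
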