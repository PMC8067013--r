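composition,mode,slope,N,Ubr_mean_V,Ubr_sd_V,tbr_mean_s,tbr_sd_s,Awat_frac_percent
POPC:POPS,voltage_controlled,48100,7,0.72,0.03,15.73e-6,0.73e-6,1.49
POPC:POPS,voltage_controlled,21600,7,0.63,0.05,28.90e-6,2.30e-6,0.81
POPC:POPS,voltage_controlled,16700,6,0.59,0.06,35.73e-6,3.70e-6,0.66
POPC:POPS,voltage_controlled,11500,7,0.55,0.04,48.49e-6,3.55e-6,0.48
POPC:POPS,voltage_controlled,7800,11,0.53,0.04,96.66e-6,4.60e-6,0.24
POPC:POPS,voltage_controlled,5500,9,0.53,0.05,96.68e-6,9.12e-6,0.24
POPC:POPS,voltage_controlled,4800,13,0.48,0.03,101.24e-6,7.39e-6,0.23
POPC:POPS,current_controlled,10e-6,3,0.27,0.08,0.61,0.19,15.92e-6
POPC:POPS,current_controlled,8e-6,5,0.52,0.23,1.47,0.51,38.47e-6
POPC:POPS,current_controlled,4e-6,5,0.63,0.17,3.56,0.94,6.59e-6
POPC:POPS,current_controlled,1e-6,6,0.43,0.16,9.90,3.70,2.37e-6
POPC:POPS,current_controlled,0.5e-6,5,0.47,0.17,20.47,8.92,1.15e-6
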