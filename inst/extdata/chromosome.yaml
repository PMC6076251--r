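# Chromosome-arm filament parameters (SI except r_um)
E_Pa: 500
G_Pa: 227
r_um: 1
kappa: 0.75
eta: 0.001
eta_b: 66
eta_s: 162
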