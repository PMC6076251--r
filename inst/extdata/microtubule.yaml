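# Microtubule parameters for drag-limited length-scaling analysis.
# G is the soft inter-protofilament shear modulus; eta_b/eta_s omitted
# (drag-dominated regime).
E_Pa: 1.2e9
G_Pa: 1.5e3
r_um: 0.0125
kappa: 0.75
eta: 0.002
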