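# High-flux hollow-fiber hemodialyzer wall
label    = highflux_fiber
geometry = open-area-wall
epsilon  = 0.0545  # open-area fraction of the blood-side surface
x_m      = 50e-6   # wall thickness, m
A_m2     = 1
S        = 1
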