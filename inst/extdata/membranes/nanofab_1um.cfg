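# Reference nanofabricated membrane: straight cylindrical pores
label    = nanofab_1um
geometry = cylindrical-nanopore
b_nm     = 10      # pore radius, nm
x_m      = 1e-6    # thickness, m (1 micron)
A_m2     = 1       # total membrane area, m^2
S        = 1       # sieving coefficient
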