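# Example run: cross-membrane effective-diffusivity comparison for the three
# toxins with measured high-flux effective diffusivities.
catalog        = builtin
membrane_a     = highflux_fiber
membrane_b     = nanofab_1um
deff_reference = builtin
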