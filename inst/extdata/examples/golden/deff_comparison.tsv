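# generated by memflux 0.1.0
# sign convention: positive flux = blood to dialysate
# report: effective diffusivity comparison (cm^2/s)
# membrane_a: highflux_fiber
# membrane_b: nanofab_1um
# d0_source: inferred from Deff in highflux_fiber
# lambda_mode: radius
# eta_exponent: 1.4
# double_hindrance: TRUE
# T_K: 310.15
# F_C_per_mol: 96485
# R_J_per_mol_K: 8.314
toxin	d0_cm2_s	k_diff_a	d_eff_a_cm2_s	k_diff_b	d_eff_b_cm2_s	ratio_b_over_a
Endothelin	1.91144e-06	7.84749e-04	1.50000e-09	7.20995e-01	1.37814e-06	9.18759e+02
Cystatin C	9.81206e-07	7.84749e-04	7.70000e-10	5.80727e-01	5.69812e-07	7.40016e+02
Interleukin-6	6.88118e-07	7.84749e-04	5.40000e-10	4.85603e-01	3.34153e-07	6.18801e+02
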