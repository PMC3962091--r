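cat7 <- toxin_catalog()
cystatin <- cat7[["Cystatin C"]]

test_that("diffusion term matches hand arithmetic, with and without the extra hindrance", {
  expect_identical(diffusion_flux(5.73e-11, 1, 0.58073, 0, 1e-6), 0)
  expect_equal(diffusion_flux(5.73e-11, 1, 0.58073, 1.199e-4, 1e-6),
               -3.990e-9, tolerance = 1e-3)
  # sign flips with the sign of delta_c
  expect_equal(diffusion_flux(5.73e-11, 1, 0.58073, -1.199e-4, 1e-6),
               -diffusion_flux(5.73e-11, 1, 0.58073, 1.199e-4, 1e-6))
  # no-double-hindrance drops exactly one factor of Kdiff
  expect_equal(diffusion_flux(5.73e-11, 1, 0.58073, 1.199e-4, 1e-6,
                              double_hindrance = FALSE) * 0.58073,
               diffusion_flux(5.73e-11, 1, 0.58073, 1.199e-4, 1e-6),
               tolerance = 1e-14)
  expect_error(diffusion_flux(1e-11, 1, 0.5, 1e-4, 0), "positive")
})

test_that("electromigration term matches hand arithmetic and reports per-valence magnitude", {
  expect_identical(electromigration_flux(5.73e-11, 1, 1.199e-4, z = 1,
                                         T_K = 310.15, delta_V = 0, x = 1e-6), 0)
  j <- electromigration_flux(5.73e-11, 1, 1.199e-4, z = 1, T_K = 310.15,
                             delta_V = 0.010, x = 1e-6)
  expect_equal(abs(j), 2.571e-9, tolerance = 1e-3)
  expect_lt(j, 0)  # literal sign: leading minus with positive potential
  # z unset -> per-valence magnitude, equal to |z = 1| result
  expect_equal(electromigration_flux(5.73e-11, 1, 1.199e-4, T_K = 310.15,
                                     delta_V = 0.010, x = 1e-6), abs(j))
  # linear in delta_V and in z
  expect_equal(electromigration_flux(5.73e-11, 1, 1.199e-4, z = 2,
                                     T_K = 310.15, delta_V = 0.010, x = 1e-6),
               2 * j, tolerance = 1e-14)
  expect_equal(electromigration_flux(5.73e-11, 1, 1.199e-4, z = 1,
                                     T_K = 310.15, delta_V = 0.040, x = 1e-6),
               4 * j, tolerance = 1e-14)
})

test_that("pH term is the literal proton-motive bracket", {
  expect_identical(ph_flux(5.73e-11, 1, 0, 1e-6, 7.4, 7.4), 0)
  # equal pH on both sides: bracket = -4.606*7.4 - 2.303*log10(7.4^2) = -38.088
  j <- ph_flux(5.73e-11, 1, 1.199e-4, 1e-6, 7.4, 7.4)
  expect_equal(j, 2.617e-7, tolerance = 1e-3)
  expect_gt(j, 0)
  # linear in Cm
  expect_equal(ph_flux(5.73e-11, 1, 3 * 1.199e-4, 1e-6, 7.4, 7.4), 3 * j,
               tolerance = 1e-14)
})

test_that("convection and ultrafiltration terms are bilinear products", {
  expect_identical(convection_flux(1, 1, 1.199e-4, 0), 0)
  expect_equal(convection_flux(1, 1, 1.199e-4, 1e-8), 1.199e-12,
               tolerance = 1e-12)
  expect_equal(convection_flux(0.5, 2, 1.199e-4, 1e-8), 1.199e-12,
               tolerance = 1e-12)

  expect_identical(ultrafiltration_flux(1, 1e-11, 1, 5000, -5000), 0)
  expect_equal(ultrafiltration_flux(1, 1e-11, 1, 5000, 0), 5e-8,
               tolerance = 1e-12)
  # additive in delta_P and delta_pi
  expect_equal(ultrafiltration_flux(1, 1e-11, 1, 3000, 2000),
               ultrafiltration_flux(1, 1e-11, 1, 3000, 0) +
                 ultrafiltration_flux(1, 1e-11, 1, 0, 2000), tolerance = 1e-14)
})

test_that("total flux sums its five terms from one coherent input set", {
  fb0 <- total_flux(cystatin, nanofab_membrane(), driving_forces())
  expect_true(all(fb0$terms == 0))
  expect_identical(fb0$J_total, 0)

  forces <- driving_forces(delta_c = -1.199e-4, delta_V = 0.010,
                           pH_blood = 7.38, pH_dialysate = 7.45, J_v = 1e-9)
  fb <- total_flux(cystatin, nanofab_membrane(), forces)
  expect_identical(fb$J_total, sum(fb$terms))
  expect_length(fb$terms, 5L)
  # each term matches the standalone function under the same inputs
  d_eff <- fb$diffusivity$d_eff_cm2_s * 1e-4
  kd <- fb$diffusivity$k_diff
  expect_equal(fb$terms[["diffusion"]],
               diffusion_flux(d_eff, 1, kd, -1.199e-4, 1e-6),
               tolerance = 1e-14)
  expect_equal(fb$terms[["electromigration"]],
               electromigration_flux(d_eff, 1, fb$c_m_mol_m3, T_K = 310.15,
                                     delta_V = 0.010, x = 1e-6),
               tolerance = 1e-14)
  expect_equal(fb$terms[["pH"]],
               ph_flux(d_eff, 1, fb$c_m_mol_m3, 1e-6, 7.38, 7.45),
               tolerance = 1e-14)
  expect_true(fb$per_z)  # valence unset in the catalog

  # a potential-only scenario: total equals the electromigration term alone
  fb_em <- total_flux(cystatin, nanofab_membrane(),
                      driving_forces(delta_V = 0.010))
  expect_identical(fb_em$J_total, fb_em$terms[["electromigration"]])
  expect_true(all(fb_em$terms[names(fb_em$terms) != "electromigration"] == 0))
})

test_that("total flux flags configuration errors explicitly", {
  expect_error(total_flux(cystatin, nanofab_membrane(),
                          driving_forces(delta_P = 5000)),
               "L_p/Omega unset")
  no_conc <- cat7[["Retinol-binding protein"]]
  expect_error(total_flux(no_conc, nanofab_membrane(),
                          driving_forces(delta_V = 0.01), d0_cm2_s = 1e-6),
               "concentration")
  expect_error(total_flux(no_conc, nanofab_membrane(), driving_forces()),
               "molar mass")
})

test_that("every flux term is linear in the membrane concentration", {
  forces <- driving_forces(delta_V = 0.020, pH_blood = 7.4, pH_dialysate = 7.4,
                           J_v = 1e-9)
  f1 <- total_flux(cystatin, nanofab_membrane(), forces)
  f3 <- total_flux(cystatin, nanofab_membrane(), forces,
                   c_m_mol_m3 = 3 * f1$c_m_mol_m3)
  # diffusion term has no Cm dependence (delta_c = 0 here); the others triple
  for (term in c("electromigration", "pH", "convection"))
    expect_equal(f3$terms[[term]], 3 * f1$terms[[term]], tolerance = 1e-12)
})

test_that("potential sweeps are exactly proportional to the applied potential", {
  grid <- seq(0.010, 0.080, by = 0.010)
  sw <- flux_sweep(cystatin, nanofab_membrane(), driving_forces(),
                   variable = "delta_V", grid = grid)
  expect_identical(nrow(sw), 8L)
  slope <- sw$electromigration / sw$delta_V
  expect_true(all(abs(slope - slope[1]) / slope[1] < 1e-12))
  expect_equal(sw$J_total, sw$electromigration, tolerance = 1e-15)

  single <- flux_sweep(cystatin, nanofab_membrane(),
                       driving_forces(delta_V = 0.010),
                       variable = "delta_V", grid = 0.010)
  fb <- total_flux(cystatin, nanofab_membrane(),
                   driving_forces(delta_V = 0.010))
  expect_equal(single$J_total, fb$J_total, tolerance = 1e-15)
  expect_error(flux_sweep(cystatin, nanofab_membrane(), driving_forces(),
                          variable = "delta_V", grid = numeric(0)), "grid")
})

test_that("thinning the membrane from 25 um to 1 um boosts electromigration 25-fold", {
  sw <- flux_sweep(cystatin, nanofab_membrane(),
                   driving_forces(delta_V = 0.010), variable = "x",
                   grid = c(25e-6, 1e-6))
  expect_equal(sw$electromigration[2] / sw$electromigration[1], 25,
               tolerance = 1e-12)
  # pH term scales identically with 1/x
  sw_ph <- flux_sweep(cystatin, nanofab_membrane(),
                      driving_forces(pH_blood = 7.4, pH_dialysate = 7.4),
                      variable = "x", grid = c(25e-6, 1e-6))
  expect_equal(sw_ph$pH[2] / sw_ph$pH[1], 25, tolerance = 1e-12)
})

test_that("membrane comparison reproduces the published diffusivity table", {
  cmp <- compare_membranes(cat7[names(highflux_deff_ref)],
                           highflux_membrane(), nanofab_membrane(),
                           d_eff_a_cm2_s = highflux_deff_ref)
  expect_identical(nrow(cmp), 3L)
  rel <- abs(cmp$d_eff_b_cm2_s - nanofab_deff_ref[cmp$toxin]) /
    nanofab_deff_ref[cmp$toxin]
  expect_true(all(rel < 0.035))
  # endothelin enhancement ratio is of order 10^3 (published table: ~9.2e2)
  endo_ratio <- cmp$ratio_b_over_a[cmp$toxin == "Endothelin"]
  expect_gt(endo_ratio, 870)
  expect_lt(endo_ratio, 970)
  # all three gain about three orders of magnitude
  expect_true(all(cmp$ratio_b_over_a > 500 & cmp$ratio_b_over_a < 1100))

  same <- compare_membranes(cat7[names(highflux_deff_ref)],
                            highflux_membrane(), highflux_membrane(),
                            d_eff_a_cm2_s = highflux_deff_ref)
  expect_equal(same$ratio_b_over_a, rep(1, 3), tolerance = 1e-14)
})
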