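test_that("lambda uses the solute radius by default and rejects excluded molecules", {
  expect_equal(lambda_ratio(4.08, 10), 0.204, tolerance = 1e-12)
  expect_equal(lambda_ratio(4.08, 10, mode = "literal"), 0.408,
               tolerance = 1e-12)
  expect_equal(lambda_ratio(1e-9, 10), 5e-11)            # vanishing solute
  expect_error(lambda_ratio(20, 10), "excluded")
  expect_error(lambda_ratio(-1, 10), "positive")
  expect_error(lambda_ratio(2, 10, mode = "literal"), NA)  # 0.2, admissible
  expect_error(lambda_ratio(12, 10, mode = "literal"), "excluded")
})

test_that("Renkin polynomial matches direct evaluation and its validity bounds", {
  expect_identical(renkin_hindrance(0), 1)
  expect_equal(renkin_hindrance(0.204), 0.58073, tolerance = 1e-5)
  expect_equal(renkin_hindrance(0.13), 0.72100, tolerance = 1e-5)
  expect_error(renkin_hindrance(-0.1), "lambda")
  expect_error(renkin_hindrance(1), "lambda")
  expect_warning(renkin_hindrance(0.65), "validity")

  # strictly decreasing, within (0, 1], on the valid range
  lam <- seq(0, 0.6, by = 0.005)
  k <- renkin_hindrance(lam)
  expect_true(all(diff(k) < 0))
  expect_true(all(k > 0 & k <= 1))
})

test_that("open-area hindrance matches direct evaluation and is monotone", {
  expect_identical(open_area_hindrance(1), 1)
  expect_equal(open_area_hindrance(0.0545), 7.848e-4, tolerance = 1e-3)
  eps <- seq(0.01, 1, by = 0.01)
  expect_true(all(diff(open_area_hindrance(eps)) > 0))
  expect_error(open_area_hindrance(0), "epsilon")
  expect_error(open_area_hindrance(1.2), "epsilon")
})

test_that("water viscosity correlation hits tabulated anchors and decreases with T", {
  expect_equal(water_viscosity(310.15), 0.6913, tolerance = 0.005)
  expect_equal(water_viscosity(293.15), 1.002, tolerance = 0.005)
  T <- seq(273.15, 373.15, by = 1)
  expect_true(all(diff(water_viscosity(T)) < 0))
  expect_error(water_viscosity(250), "range")
  expect_error(water_viscosity(400), "range")
})

test_that("free diffusivity follows the molar-volume correlation and its scaling law", {
  expect_equal(free_diffusivity(9740, 0.6913, 1.4), 9.95e-7, tolerance = 1e-3)
  expect_equal(free_diffusivity(9740, 0.6913, 1.14), 9.04e-7, tolerance = 1e-3)
  # V_M doubling scales D0 by 2^-0.589
  d1 <- free_diffusivity(5000, 0.7)
  d2 <- free_diffusivity(10000, 0.7)
  expect_equal(d2 / d1, 2^-0.589, tolerance = 1e-12)
  expect_error(free_diffusivity(-1, 0.7), "positive")
  expect_error(free_diffusivity(5000, 0), "positive")
})

test_that("effective diffusivity is the hindered product and inverts exactly", {
  r <- effective_diffusivity(9.812e-7, 0.58073)
  expect_equal(r$d_eff_cm2_s, 5.698e-7, tolerance = 1e-3)
  # within 1% of the published nanofabricated value for cystatin C
  expect_lt(abs(r$d_eff_cm2_s - 5.73e-7) / 5.73e-7, 0.01)
  expect_identical(effective_diffusivity(3e-6, 1)$d_eff_cm2_s, 3e-6)

  set.seed(5)
  for (i in 1:25) {
    d0 <- 10^stats::runif(1, -10, -4)
    k <- stats::runif(1, 1e-6, 1)
    r <- effective_diffusivity(d0, k)
    expect_lte(r$d_eff_cm2_s, r$d0_cm2_s)                  # Deff <= D0 always
    expect_identical(infer_d0(r$d_eff_cm2_s, k), d0 * k / k)
    expect_lt(abs(infer_d0(r$d_eff_cm2_s, k) - d0) / d0, 1e-14)
  }
  expect_equal(infer_d0(15e-10, 7.848e-4), 1.911e-6, tolerance = 1e-3)
  expect_error(infer_d0(1e-9, 0), "positive")
  expect_error(effective_diffusivity(1e-6, 1.5), "k_diff")
})

test_that("cross-membrane route reproduces the published nanofabricated diffusivities", {
  # infer D0 from the high-flux wall measurement, re-apply the nanopore
  # hindrance: agreement with the published values within 3.5% overall
  k_open <- open_area_hindrance(0.0545)
  cat7 <- toxin_catalog()
  tol <- c("Endothelin" = 0.01, "Cystatin C" = 0.01, "Interleukin-6" = 0.035)
  for (nm in names(highflux_deff_ref)) {
    d0 <- infer_d0(highflux_deff_ref[[nm]], k_open)
    lam <- lambda_ratio(cat7[[nm]]$d_max_nm, 10)
    pred <- effective_diffusivity(d0, renkin_hindrance(lam))$d_eff_cm2_s
    expect_lt(abs(pred - nanofab_deff_ref[[nm]]) / nanofab_deff_ref[[nm]],
              tol[[nm]])
  }
})

test_that("membrane specs validate geometry-appropriate parameters", {
  expect_error(membrane_spec("m", "cylindrical-nanopore", x_m = 1e-6),
               "pore radius")
  expect_error(membrane_spec("m", "cylindrical-nanopore", b_nm = 10,
                             epsilon = 0.1, x_m = 1e-6), "not a parameter")
  expect_error(membrane_spec("m", "open-area-wall", x_m = 1e-6), "epsilon")
  expect_error(membrane_spec("m", "open-area-wall", epsilon = 0.05, x_m = -1),
               "positive")
  expect_error(membrane_spec("m", "open-area-wall", epsilon = 0.05, x_m = 1e-6,
                             S = 2), "S must be")

  nano <- nanofab_membrane()
  expect_identical(nano$b_nm, 10)
  expect_identical(nano$x_m, 1e-6)
  hf <- highflux_membrane()
  expect_identical(hf$epsilon, 0.0545)
  expect_identical(hf$x_m, 50e-6)
})

test_that("membrane hindrance dispatches on geometry", {
  k_nano <- membrane_kdiff(nanofab_membrane(), d_max_nm = 4.08)
  expect_identical(k_nano$formula, "renkin")
  expect_equal(k_nano$lam, 0.204)
  expect_equal(k_nano$k_diff, renkin_hindrance(0.204))
  k_open <- membrane_kdiff(highflux_membrane())
  expect_identical(k_open$formula, "open-area")
  expect_equal(k_open$k_diff, open_area_hindrance(0.0545))
  expect_error(membrane_kdiff(nanofab_membrane()), "d_max_nm")
})

test_that("bundled membrane files parse to the bundled constructors", {
  nano <- read_membrane(system.file("extdata", "membranes", "nanofab_1um.cfg",
                                    package = "memflux"))
  expect_identical(nano$geometry, "cylindrical-nanopore")
  expect_identical(nano$b_nm, 10)
  expect_identical(nano$x_m, 1e-6)
  expect_identical(nano$A_m2, 1)
  hf <- read_membrane(system.file("extdata", "membranes", "highflux_fiber.cfg",
                                  package = "memflux"))
  expect_identical(hf$epsilon, 0.0545)
  expect_identical(hf$x_m, 5e-5)

  bad <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("geometry = open-area-wall", "this line has no equals sign"),
             bad)
  expect_error(read_membrane(bad), "malformed")
})
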