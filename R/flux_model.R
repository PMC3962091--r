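#' Driving forces acting across a membrane
#'
#' Collects the gradients and flows that drive solute transport in the
#' expanded Nernst-Planck flux decomposition. Gradients are treated as
#' uniform across the membrane thickness: dV/dx = delta_V / x,
#' dc/dx = delta_c / x (no spatial discretisation).
#'
#' Sign convention: positive flux is blood-to-dialysate. The flux terms keep
#' the leading minus signs of the transport equation, so `delta_c` and
#' `delta_V` are downstream-minus-upstream (dialysate minus blood)
#' differences: a concentration excess on the blood side enters as a negative
#' `delta_c` and yields a positive (clearing) diffusion flux.
#'
#' @param delta_c Transmembrane concentration difference, mol/m^3. Default 0.
#' @param delta_V Applied electric potential difference, V. Default 0.
#' @param pH_blood,pH_dialysate pH on each side, in `[0, 14]`; `NA` disables
#'   the pH term.
#' @param J_v Volumetric (convective) flux, m^3/s. Default 0.
#' @param delta_P Hydraulic pressure difference, Pa. Default 0.
#' @param delta_pi Osmotic pressure difference, Pa. Default 0.
#' @param T_K Temperature, K. Default 310.15 (37 C).
#' @return Object of class `driving_forces`.
#' @export
driving_forces <- function(delta_c = 0, delta_V = 0, pH_blood = NA_real_,
                           pH_dialysate = NA_real_, J_v = 0, delta_P = 0,
                           delta_pi = 0, T_K = 310.15) {
  if (T_K <= 0) stop("T_K must be positive", call. = FALSE)
  for (p in c(pH_blood, pH_dialysate))
    if (!is.na(p) && (p < 0 || p > 14))
      stop("pH values must lie in [0, 14]", call. = FALSE)
  structure(list(delta_c = delta_c, delta_V = delta_V, pH_blood = pH_blood,
                 pH_dialysate = pH_dialysate, J_v = J_v, delta_P = delta_P,
                 delta_pi = delta_pi, T_K = T_K),
            class = "driving_forces")
}

#' Individual terms of the expanded Nernst-Planck flux
#'
#' The transmembrane solute flux is decomposed into five additive terms, each
#' a transport coefficient times a driving force (the irreversible-
#' thermodynamics, black-box view of the membrane):
#'
#' * `diffusion_flux()`: -Deff A Kdiff (delta_c / x). Note the hindrance
#'   factor multiplies Deff even though Deff = Kdiff D0 already contains it —
#'   this is the literal published form and the default; set
#'   `double_hindrance = FALSE` to drop the extra factor.
#' * `electromigration_flux()`: -Deff A Cm z F/(R T) (delta_V / x). When the
#'   valence is unset (`z = NA`) the per-unit-valence magnitude is returned.
#' * `ph_flux()`: -(Deff A Cm / x) (-4.606 pH1 - 2.303 log10(pH2^2)), the
#'   literal reading of the published proton-motive term; which side each pH
#'   refers to is configurable and recorded (see the methods vignette for why
#'   this term is treated with caution).
#' * `convection_flux()`: Kconv A Cm Jv.
#' * `ultrafiltration_flux()`: Omega Lp A (delta_P + delta_pi).
#'
#' All inputs are SI: Deff in m^2/s, areas in m^2, concentrations in mol/m^3,
#' thickness in m, potential in V, pressures in Pa; fluxes come out in mol/s.
#' Constants F = 96485 C/mol and R = 8.314 J/(mol K) ([memflux_constants()]).
#'
#' @param d_eff Effective diffusivity, m^2/s.
#' @param A Membrane area, m^2.
#' @param k_diff Diffusional hindrance factor (dimensionless).
#' @param delta_c Concentration difference, mol/m^3.
#' @param x Membrane thickness, m, positive.
#' @param double_hindrance Keep the literal extra Kdiff factor in the
#'   diffusion term? Default `TRUE`.
#' @return Flux in mol/s.
#' @examples
#' diffusion_flux(5.73e-11, 1, 0.58073, 1.199e-4, 1e-6)
#' electromigration_flux(5.73e-11, 1, 1.199e-4, z = 1, T_K = 310.15,
#'                       delta_V = 0.010, x = 1e-6)
#' @export
diffusion_flux <- function(d_eff, A, k_diff, delta_c, x,
                           double_hindrance = TRUE) {
  if (any(x <= 0)) stop("x must be positive", call. = FALSE)
  kd <- if (double_hindrance) k_diff else 1
  -d_eff * A * kd * (delta_c / x)
}

#' @rdname diffusion_flux
#' @param c_m Solute concentration at the membrane, mol/m^3.
#' @param z Signed valence; `NA` (unset) reports the per-valence magnitude.
#' @param T_K Temperature, K.
#' @param delta_V Potential difference, V.
#' @export
electromigration_flux <- function(d_eff, A, c_m, z = NA_real_, T_K,
                                  delta_V, x) {
  if (any(x <= 0)) stop("x must be positive", call. = FALSE)
  if (any(T_K <= 0)) stop("T_K must be positive", call. = FALSE)
  k <- memflux_constants()
  per_z <- -d_eff * A * c_m * k$F_faraday / (k$R_gas * T_K) * (delta_V / x)
  if (is.na(z)) abs(per_z) else z * per_z
}

#' @rdname diffusion_flux
#' @param pH_1,pH_2 The two pH values entering the proton-motive bracket;
#'   by default pH_1 is the blood side and pH_2 the dialysate side.
#' @export
ph_flux <- function(d_eff, A, c_m, x, pH_1, pH_2) {
  if (any(x <= 0)) stop("x must be positive", call. = FALSE)
  bracket <- -4.606 * pH_1 - 2.303 * log10(pH_2^2)
  -(d_eff * A * c_m / x) * bracket
}

#' @rdname diffusion_flux
#' @param k_conv Convective hindrance coefficient.
#' @param J_v Volumetric flux, m^3/s.
#' @export
convection_flux <- function(k_conv, A, c_m, J_v) {
  k_conv * A * c_m * J_v
}

#' @rdname diffusion_flux
#' @param omega Solute-coupling coefficient Omega.
#' @param L_p Hydraulic permeability, m/(s Pa).
#' @param delta_P Hydraulic pressure difference, Pa.
#' @param delta_pi Osmotic pressure difference, Pa.
#' @export
ultrafiltration_flux <- function(omega, L_p, A, delta_P, delta_pi) {
  omega * L_p * A * (delta_P + delta_pi)
}

#' Full five-term flux decomposition for one toxin/membrane/conditions triple
#'
#' Computes the solute's effective diffusivity in the given membrane, then
#' evaluates all five Nernst-Planck terms from one coherent input set and
#' sums them. The result records the inputs, the diffusivity provenance, the
#' constants, and every flag, so a report can restate the exact convention
#' used.
#'
#' The free diffusivity D0 is taken from `d0_cm2_s` if supplied; otherwise it
#' is predicted from the toxin's molar mass via the molar-volume route
#' ([estimate_molar_volume()], [free_diffusivity()] at the scenario
#' temperature).
#'
#' @param toxin A [toxin_species()].
#' @param membrane A [membrane_spec()].
#' @param forces A [driving_forces()].
#' @param d0_cm2_s Optional free diffusivity override, cm^2/s.
#' @param c_m_mol_m3 Optional membrane concentration override, mol/m^3;
#'   default is the toxin's `c_molar`.
#' @param eta_exponent Viscosity exponent for the D0 correlation.
#' @param lambda_mode Solute-size convention for lambda, see [lambda_ratio()].
#' @param double_hindrance Literal extra Kdiff in the diffusion term?
#' @param ph_order Which pH fills each slot of the proton-motive bracket:
#'   `"blood-dialysate"` (default: pH_1 = blood, pH_2 = dialysate) or
#'   `"dialysate-blood"`. Recorded in the result's flags.
#' @return Object of class `flux_breakdown`: named terms (mol/s), their sum
#'   `J_total`, and full provenance. When the toxin valence is unset the
#'   electromigration term is the per-unit-valence magnitude and is flagged
#'   `per_z = TRUE`.
#' @examples
#' cc <- toxin_catalog()[["Cystatin C"]]
#' fb <- total_flux(cc, nanofab_membrane(), driving_forces(delta_V = 0.010))
#' fb$J_total
#' @export
total_flux <- function(toxin, membrane, forces, d0_cm2_s = NULL,
                       c_m_mol_m3 = NULL, eta_exponent = 1.4,
                       lambda_mode = c("radius", "literal"),
                       double_hindrance = TRUE,
                       ph_order = c("blood-dialysate", "dialysate-blood")) {
  stopifnot(inherits(toxin, "toxin_species"),
            inherits(membrane, "membrane_spec"),
            inherits(forces, "driving_forces"))
  lambda_mode <- match.arg(lambda_mode)
  ph_order <- match.arg(ph_order)

  hin <- membrane_kdiff(membrane, d_max_nm = toxin$d_max_nm,
                        lambda_mode = lambda_mode)
  if (is.null(d0_cm2_s)) {
    if (is.na(toxin$molar_mass))
      stop("toxin '", toxin$name, "' has no molar mass; supply d0_cm2_s or ",
           "a molar mass to predict D0", call. = FALSE)
    v_m <- estimate_molar_volume(toxin$molar_mass)
    eta <- water_viscosity(forces$T_K)
    d0_cm2_s <- free_diffusivity(v_m, eta, eta_exponent)
    diffu <- effective_diffusivity(d0_cm2_s, hin$k_diff, hindrance = hin,
                                   v_m = v_m, eta = eta, T_K = forces$T_K)
  } else {
    diffu <- effective_diffusivity(d0_cm2_s, hin$k_diff, hindrance = hin,
                                   T_K = forces$T_K)
  }
  d_eff <- diffu$d_eff_cm2_s * .cm2_to_m2  # SI for the flux terms

  c_m <- c_m_mol_m3 %||% toxin$c_molar
  if (is.na(c_m))
    stop("no membrane concentration available for '", toxin$name,
         "'; set c_normal in the catalog or pass c_m_mol_m3", call. = FALSE)

  A <- membrane$A_m2; x <- membrane$x_m

  J_diff <- diffusion_flux(d_eff, A, hin$k_diff, forces$delta_c, x,
                           double_hindrance = double_hindrance)
  J_em <- if (forces$delta_V == 0) 0 else
    electromigration_flux(d_eff, A, c_m, z = toxin$z, T_K = forces$T_K,
                          delta_V = forces$delta_V, x = x)
  J_ph <- if (is.na(forces$pH_blood) || is.na(forces$pH_dialysate)) 0 else {
    if (ph_order == "blood-dialysate")
      ph_flux(d_eff, A, c_m, x, forces$pH_blood, forces$pH_dialysate)
    else
      ph_flux(d_eff, A, c_m, x, forces$pH_dialysate, forces$pH_blood)
  }
  J_conv <- convection_flux(membrane$K_conv, A, c_m, forces$J_v)
  if ((forces$delta_P != 0 || forces$delta_pi != 0) &&
      (is.na(membrane$L_p) || is.na(membrane$Omega)))
    stop("ultrafiltration driving force set but membrane L_p/Omega unset",
         call. = FALSE)
  J_uf <- if (forces$delta_P == 0 && forces$delta_pi == 0) 0 else
    ultrafiltration_flux(membrane$Omega, membrane$L_p, A,
                         forces$delta_P, forces$delta_pi)

  terms <- c(diffusion = J_diff, electromigration = J_em, pH = J_ph,
             convection = J_conv, ultrafiltration = J_uf) + 0  # normalize -0
  structure(list(terms = terms, J_total = sum(terms),
                 per_z = is.na(toxin$z) && forces$delta_V != 0,
                 toxin = toxin, membrane = membrane, forces = forces,
                 diffusivity = diffu, c_m_mol_m3 = c_m,
                 constants = memflux_constants(),
                 flags = list(eta_exponent = eta_exponent,
                              lambda_mode = lambda_mode,
                              double_hindrance = double_hindrance,
                              ph_order = ph_order)),
            class = "flux_breakdown")
}

#' @export
print.flux_breakdown <- function(x, ...) {
  cat(sprintf("<flux_breakdown> %s through %s (positive = blood to dialysate)\n",
              x$toxin$name, x$membrane$label))
  lab <- names(x$terms)
  lab[lab == "electromigration" & x$per_z] <- "electromigration (|per z|)"
  for (i in seq_along(x$terms))
    cat(sprintf("  %-26s %+.4e mol/s\n", lab[i], x$terms[i]))
  cat(sprintf("  %-26s %+.4e mol/s\n", "TOTAL", x$J_total))
  cat(sprintf("  [Deff %.4g cm^2/s, Kdiff %.4g, Cm %.4g mol/m^3, x %g um]\n",
              x$diffusivity$d_eff_cm2_s, x$diffusivity$k_diff, x$c_m_mol_m3,
              x$membrane$x_m * 1e6))
  invisible(x)
}

#' Parametric sweep of the flux decomposition
#'
#' Re-evaluates [total_flux()] over a grid of one scenario variable: the
#' applied potential (`"delta_V"`, grid in volts), the blood-side pH
#' (`"pH"`, dialysate pH held at the scenario value), or the membrane
#' thickness (`"x"`, grid in metres). Potential sweeps are affine in the
#' potential; thickness sweeps scale the gradient-driven terms as 1/x.
#'
#' @inheritParams total_flux
#' @param variable One of `"delta_V"`, `"pH"`, `"x"`.
#' @param grid Numeric grid of values for `variable`; non-empty.
#' @param ... Passed to [total_flux()].
#' @return A data.frame of class `flux_sweep`: one row per grid point with
#'   the swept value, the five term columns (mol/s) and `J_total`.
#' @examples
#' cc <- toxin_catalog()[["Cystatin C"]]
#' sw <- flux_sweep(cc, nanofab_membrane(), driving_forces(),
#'                  variable = "delta_V", grid = seq(0.01, 0.08, 0.01))
#' sw$electromigration / sw$delta_V   # constant: affine in the potential
#' @export
flux_sweep <- function(toxin, membrane, forces,
                       variable = c("delta_V", "pH", "x"), grid, ...) {
  variable <- match.arg(variable)
  if (length(grid) == 0L || any(!is.finite(grid)))
    stop("grid must be non-empty and finite", call. = FALSE)
  rows <- lapply(grid, function(g) {
    f <- forces; m <- membrane
    if (variable == "delta_V") f$delta_V <- g
    else if (variable == "pH") {
      f$pH_blood <- g
      if (is.na(f$pH_dialysate)) f$pH_dialysate <- g
    } else m$x_m <- g
    fb <- total_flux(toxin, m, f, ...)
    data.frame(value = g, t(fb$terms), J_total = fb$J_total)
  })
  out <- do.call(rbind, rows)
  names(out)[1] <- variable
  class(out) <- c("flux_sweep", "data.frame")
  attr(out, "variable") <- variable
  attr(out, "toxin") <- toxin$name
  attr(out, "membrane") <- membrane$label
  out
}

#' Compare effective diffusivities across two membranes
#'
#' For each toxin, computes Deff under membrane A and membrane B and their
#' ratio (B over A). The free diffusivity D0 of each toxin is either
#' predicted from its molar mass, or — when `d_eff_a_cm2_s` supplies measured
#' effective diffusivities under membrane A — inferred by [infer_d0()] from
#' those measurements and membrane A's hindrance, which makes the B column a
#' cross-membrane prediction anchored to data.
#'
#' @param toxins A `toxin_catalog` or list of [toxin_species()].
#' @param membrane_a,membrane_b Two [membrane_spec()]s.
#' @param d_eff_a_cm2_s Optional named numeric vector (names = toxin names)
#'   of measured Deff under membrane A, cm^2/s.
#' @param lambda_mode Passed to [lambda_ratio()].
#' @param eta_exponent Passed to [free_diffusivity()] when predicting D0.
#' @param T_K Temperature for viscosity when predicting D0.
#' @return Data.frame of class `membrane_comparison` with columns `toxin`,
#'   `d0_cm2_s`, `d0_source`, `k_diff_a`, `d_eff_a_cm2_s`, `k_diff_b`,
#'   `d_eff_b_cm2_s`, `ratio_b_over_a`.
#' @examples
#' ref <- c("Endothelin" = 15e-10, "Cystatin C" = 7.7e-10,
#'          "Interleukin-6" = 5.4e-10)
#' compare_membranes(toxin_catalog()[names(ref)], highflux_membrane(),
#'                   nanofab_membrane(), d_eff_a_cm2_s = ref)
#' @export
compare_membranes <- function(toxins, membrane_a, membrane_b,
                              d_eff_a_cm2_s = NULL,
                              lambda_mode = c("radius", "literal"),
                              eta_exponent = 1.4, T_K = 310.15) {
  lambda_mode <- match.arg(lambda_mode)
  if (inherits(toxins, "toxin_species")) toxins <- list(toxins)
  rows <- lapply(toxins, function(t) {
    ka <- membrane_kdiff(membrane_a, t$d_max_nm, lambda_mode)
    kb <- membrane_kdiff(membrane_b, t$d_max_nm, lambda_mode)
    if (!is.null(d_eff_a_cm2_s)) {
      if (!t$name %in% names(d_eff_a_cm2_s))
        stop("no measured Deff under membrane A for '", t$name, "'",
             call. = FALSE)
      da <- unname(d_eff_a_cm2_s[[t$name]])
      d0 <- infer_d0(da, ka$k_diff)
      src <- sprintf("inferred from Deff in %s", membrane_a$label)
    } else {
      if (is.na(t$molar_mass))
        stop("toxin '", t$name, "' has no molar mass to predict D0; supply ",
             "d_eff_a_cm2_s", call. = FALSE)
      d0 <- free_diffusivity(estimate_molar_volume(t$molar_mass),
                             water_viscosity(T_K), eta_exponent)
      da <- d0 * ka$k_diff
      src <- "predicted from molar volume"
    }
    data.frame(toxin = t$name, d0_cm2_s = d0, d0_source = src,
               k_diff_a = ka$k_diff, d_eff_a_cm2_s = da,
               k_diff_b = kb$k_diff, d_eff_b_cm2_s = d0 * kb$k_diff,
               ratio_b_over_a = (d0 * kb$k_diff) / da)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("membrane_comparison", "data.frame")
  attr(out, "membrane_a") <- membrane_a$label
  attr(out, "membrane_b") <- membrane_b$label
  out
}
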