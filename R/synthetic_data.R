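#' Generate a synthetic structure with an exactly known diameter
#'
#' Builds a PDB-formatted point set whose diameter (maximum pairwise
#' distance) equals `diameter` by construction: two anchor atoms sit exactly
#' `diameter` apart along z, and every other atom is rejection-sampled
#' strictly inside the open ball whose poles are the anchors, with a small
#' margin so that rounding coordinates to the PDB's three decimals cannot
#' create a longer pair or shorten the anchors. Deterministic for a fixed
#' seed. The emitted text uses standard fixed-column ATOM records, so these
#' fixtures double as parser tests for [read_structure()].
#'
#' @param diameter Target diameter in Angstrom, positive; values with at most
#'   3 decimals are preserved exactly through the PDB text round trip.
#' @param n_atoms Number of atoms, at least 2.
#' @param seed Integer seed; same seed gives byte-identical output.
#' @param element Element symbol for all atoms; default `"C"`.
#' @return List with `coords` (n x 3 matrix, Angstrom), `pdb_text` (single
#'   string of ATOM records + END), and `diameter` as requested.
#' @examples
#' s <- synthetic_structure(57.95, n_atoms = 500, seed = 7)
#' max_dimension(s$coords)$d_max_A  # 57.95 exactly
#' @export
synthetic_structure <- function(diameter, n_atoms, seed = 1L, element = "C") {
  if (n_atoms < 2L) stop("n_atoms must be at least 2", call. = FALSE)
  if (diameter <= 0) stop("diameter must be positive", call. = FALSE)
  r <- diameter / 2
  margin <- min(0.01, r / 10)  # absorbs the <= 0.001 A rounding perturbation
  coords <- with_local_seed(seed, {
    m <- matrix(0, n_atoms, 3L)
    m[1L, ] <- c(0, 0, 0)
    m[2L, ] <- c(0, 0, diameter)
    center <- c(0, 0, r)
    i <- 3L
    while (i <= n_atoms) {
      p <- stats::runif(3L, -r, r)
      # strictly inside the ball around the anchors' midpoint, with margin;
      # any two such points, or such a point and an anchor, are < diameter apart
      if (sum(p^2) < (r - margin)^2) {
        m[i, ] <- center + p
        i <- i + 1L
      }
    }
    m
  })
  coords <- round(coords, 3L)
  lines <- vapply(seq_len(n_atoms), function(i) {
    sprintf("ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, element, "SYN", "A", i, coords[i, 1L], coords[i, 2L],
            coords[i, 3L], 1.00, 0.00, element)
  }, character(1L))
  list(coords = coords, pdb_text = paste(c(lines, "END", ""), collapse = "\n"),
       diameter = diameter)
}

# straight-line arithmetic oracle for the five flux terms; deliberately does
# not call any flux_model function so scenarios can cross-check the pipeline
.oracle_flux <- function(d_eff_m2_s, A, k_diff, c_m, z, T_K, delta_c, delta_V,
                         pH_1, pH_2, k_conv, J_v, omega, L_p, delta_P,
                         delta_pi, x) {
  Fc <- 96485; Rg <- 8.314
  J1 <- -(d_eff_m2_s * A * k_diff * delta_c) / x
  J2 <- -(d_eff_m2_s * A * c_m * z * Fc * delta_V) / (Rg * T_K * x)
  J3 <- if (is.na(pH_1) || is.na(pH_2)) 0 else
    -(d_eff_m2_s * A * c_m / x) * (-4.606 * pH_1 - 2.303 * log10(pH_2 * pH_2))
  J4 <- k_conv * A * c_m * J_v
  J5 <- if (is.na(omega) || is.na(L_p)) 0 else
    omega * L_p * A * (delta_P + delta_pi)
  c(diffusion = J1, electromigration = J2, pH = J3, convection = J4,
    ultrafiltration = J5)
}

#' Generate a transport scenario with known ground truth
#'
#' Packages a toxin, membrane and set of driving forces together with the
#' true free diffusivity and the expected flux breakdown, the latter computed
#' by an independent straight-line arithmetic oracle (plain transcription of
#' the five flux formulas, sharing no code with [total_flux()]). Used for
#' parameter-recovery tests: [infer_d0()] must recover `true_d0` exactly and
#' each pipeline flux term must match the oracle to near machine precision.
#'
#' @param true_d0_cm2_s Ground-truth free diffusivity, cm^2/s.
#' @param membrane A [membrane_spec()].
#' @param toxin A [toxin_species()].
#' @param forces A [driving_forces()].
#' @return Object of class `synthetic_scenario`: the inputs plus `k_diff`,
#'   `expected_d_eff_cm2_s`, and `expected_terms` / `expected_total` (mol/s;
#'   electromigration evaluated at unit valence when the toxin's z is unset).
#' @examples
#' sc <- synthetic_scenario(9.95e-7, nanofab_membrane(),
#'                          toxin_catalog()[["Cystatin C"]],
#'                          driving_forces(delta_V = 0.010))
#' infer_d0(sc$expected_d_eff_cm2_s, sc$k_diff)  # recovers 9.95e-7
#' @export
synthetic_scenario <- function(true_d0_cm2_s, membrane, toxin, forces) {
  stopifnot(inherits(membrane, "membrane_spec"),
            inherits(toxin, "toxin_species"),
            inherits(forces, "driving_forces"))
  # hindrance by direct formula, not via membrane_kdiff
  k_diff <- if (membrane$geometry == "cylindrical-nanopore") {
    lam <- (toxin$d_max_nm / 2) / membrane$b_nm
    1.0 - 2.3 * lam + 1.154 * lam^2 + 0.224 * lam^3
  } else {
    (membrane$epsilon / (2 - membrane$epsilon))^2
  }
  d_eff_cm2_s <- k_diff * true_d0_cm2_s
  z <- if (is.na(toxin$z)) 1 else toxin$z
  c_m <- toxin$c_molar
  if (is.na(c_m))
    stop("scenario toxin needs a molar concentration", call. = FALSE)
  terms <- .oracle_flux(d_eff_cm2_s * 1e-4, membrane$A_m2, k_diff, c_m, z,
                        forces$T_K, forces$delta_c, forces$delta_V,
                        forces$pH_blood, forces$pH_dialysate,
                        membrane$K_conv, forces$J_v, membrane$Omega,
                        membrane$L_p, forces$delta_P, forces$delta_pi,
                        membrane$x_m)
  structure(list(true_d0_cm2_s = true_d0_cm2_s, membrane = membrane,
                 toxin = toxin, forces = forces, k_diff = k_diff,
                 expected_d_eff_cm2_s = d_eff_cm2_s,
                 expected_terms = terms, expected_total = sum(terms)),
            class = "synthetic_scenario")
}

#' Write test fixtures to a directory
#'
#' Emits a small set of synthetic PDB structures (known diameters) and a
#' scenario table generated from [synthetic_scenario()] ground truths.
#' Deterministic for a fixed seed.
#'
#' @param out_dir Output directory, created if needed.
#' @param seed Integer seed.
#' @return Invisibly, the paths written.
#' @export
make_fixtures <- function(out_dir, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  specs <- list(c(diameter = 10, n = 2), c(diameter = 26, n = 120),
                c(diameter = 57.95, n = 500))
  paths <- character(0)
  for (i in seq_along(specs)) {
    s <- synthetic_structure(specs[[i]][["diameter"]],
                             n_atoms = specs[[i]][["n"]],
                             seed = seed + i)
    p <- file.path(out_dir, sprintf("synthetic_d%05.1fA.pdb",
                                    specs[[i]][["diameter"]]))
    writeLines(sub("\n$", "", s$pdb_text), p)
    paths <- c(paths, p)
  }
  cat7 <- toxin_catalog()
  sc <- synthetic_scenario(9.95e-7, nanofab_membrane(),
                           cat7[["Cystatin C"]],
                           driving_forces(delta_V = 0.010))
  tab <- data.frame(toxin = sc$toxin$name, true_d0_cm2_s = sc$true_d0_cm2_s,
                    k_diff = sc$k_diff,
                    expected_d_eff_cm2_s = sc$expected_d_eff_cm2_s,
                    t(sc$expected_terms), expected_total = sc$expected_total)
  p <- file.path(out_dir, "synthetic_scenarios.tsv")
  utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  invisible(paths)
}
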