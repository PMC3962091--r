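# Independent oracles and small generators shared across test files.

# brute-force point-set diameter: full distance matrix via stats::dist,
# a code path entirely separate from max_dimension()'s blocked arithmetic
brute_diameter <- function(xyz) max(stats::dist(xyz))

# uniformly random proper rotation matrix (QR of a Gaussian matrix)
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

random_points <- function(n, scale = 50) {
  matrix(stats::runif(3 * n, -scale, scale), ncol = 3)
}

# the three toxins with published effective diffusivities in the high-flux
# hemodialyzer wall (cm^2/s), used for cross-membrane checks
highflux_deff_ref <- c("Endothelin" = 15e-10, "Cystatin C" = 7.7e-10,
                       "Interleukin-6" = 5.4e-10)
nanofab_deff_ref <- c("Endothelin" = 13.87e-7, "Cystatin C" = 5.73e-7,
                      "Interleukin-6" = 3.45e-7)
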