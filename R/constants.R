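#' Physical constants used throughout the flux model
#'
#' Faraday constant, gas constant, and default physiological temperature, as a
#' named list. The flux equations use these exact values; they are recorded in
#' every [flux_breakdown()] object so a report can state the constants it used.
#'
#' @return Named list with elements `F_faraday` (96485 C/mol), `R_gas`
#'   (8.314 J/(mol K)) and `T_body` (310.15 K, i.e. 37 degrees C).
#' @examples
#' memflux_constants()$F_faraday
#' @export
memflux_constants <- function() {
  list(F_faraday = 96485, R_gas = 8.314, T_body = 310.15)
}

# cm^2/s -> m^2/s
.cm2_to_m2 <- 1e-4

# run expr with a fixed RNG seed, restoring the caller's RNG state afterwards
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
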