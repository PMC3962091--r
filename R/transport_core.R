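#' Solute-to-pore size ratio lambda
#'
#' For a cylindrical pore of radius `b`, the hindrance polynomial is evaluated
#' at lambda = a/b where `a` is the solute radius. The solute radius is taken
#' as half the molecule's maximal linear dimension (`d_max/2`); this radius
#' convention is the package default because it is the one consistent with the
#' open-area hindrance route across membranes (see the methods vignette). A
#' `literal` mode using the full d_max as the size is available for
#' comparison.
#'
#' @param d_max_nm Maximal molecular dimension in nm, positive.
#' @param b_nm Pore radius in nm, positive.
#' @param mode `"radius"` (default, lambda = (d_max/2)/b) or `"literal"`
#'   (lambda = d_max/b).
#' @return lambda, dimensionless, in `[0, 1)`.
#' @examples
#' lambda_ratio(4.08, 10)   # 0.204
#' @export
lambda_ratio <- function(d_max_nm, b_nm, mode = c("radius", "literal")) {
  mode <- match.arg(mode)
  if (any(d_max_nm <= 0) || any(b_nm <= 0))
    stop("d_max_nm and b_nm must be positive", call. = FALSE)
  r <- if (mode == "radius") d_max_nm / 2 else d_max_nm
  lam <- r / b_nm
  if (any(lam >= 1))
    stop("molecule excluded: solute size (", signif(max(r), 4),
         " nm) reaches the pore radius (", b_nm, " nm)", call. = FALSE)
  lam
}

#' Renkin hindrance polynomial for cylindrical pores
#'
#' Diffusional hindrance of a spherical solute in a liquid-filled cylindrical
#' pore: Kdiff = 1 - 2.3 lambda + 1.154 lambda^2 + 0.224 lambda^3. The
#' polynomial is a centerline-transport fit valid for lambda up to about 0.6;
#' a warning is issued above that.
#'
#' @param lam lambda = solute radius / pore radius, in `[0, 1)`.
#' @return Kdiff, dimensionless in (0, 1].
#' @examples
#' renkin_hindrance(0)      # 1
#' renkin_hindrance(0.204)  # 0.58073
#' @export
renkin_hindrance <- function(lam) {
  if (any(lam < 0) || any(lam >= 1))
    stop("lambda must be in [0, 1)", call. = FALSE)
  if (any(lam > 0.6))
    warning("lambda > 0.6: hindrance polynomial outside its validity range",
            call. = FALSE)
  1.0 - 2.3 * lam + 1.154 * lam^2 + 0.224 * lam^3
}

#' Open-area hindrance of a porous wall
#'
#' Hindrance of diffusion across a wall whose face has open-area fraction
#' epsilon: Kdiff = (epsilon / (2 - epsilon))^2. Used for the hollow-fiber
#' hemodialyzer wall, whose inner surface has about 5.45% open area.
#'
#' @param epsilon Open-area fraction in (0, 1].
#' @return Kdiff, dimensionless in (0, 1].
#' @examples
#' open_area_hindrance(0.0545)  # 7.85e-4
#' @export
open_area_hindrance <- function(epsilon) {
  if (any(epsilon <= 0) || any(epsilon > 1))
    stop("epsilon must be in (0, 1]", call. = FALSE)
  (epsilon / (2 - epsilon))^2
}

#' Viscosity of liquid water
#'
#' Vogel-type correlation eta(T) = 2.414e-2 * 10^(247.8 / (T - 140)) cP,
#' anchored to tabulated values (1.002 cP at 20 C, 0.691 cP at 37 C), valid
#' over the liquid range at ambient pressure.
#'
#' @param T_K Temperature in kelvin, in `[273.15, 373.15]`.
#' @return Dynamic viscosity in centipoise (mPa s).
#' @examples
#' water_viscosity(310.15)  # ~0.691 cP at body temperature
#' @export
water_viscosity <- function(T_K) {
  if (any(T_K < 273.15) || any(T_K > 373.15))
    stop("temperature outside liquid-water range [273.15, 373.15] K",
         call. = FALSE)
  2.414e-2 * 10^(247.8 / (T_K - 140))
}

#' Free-solution diffusivity from molar volume
#'
#' Empirical correlation D0 = 13.26e-5 / (eta^p * V_M^0.589) cm^2/s, with
#' viscosity eta in cP and molar volume V_M in cm^3/mol. The viscosity
#' exponent `p` defaults to 1.4; the classical dilute-aqueous correlation of
#' this family uses 1.14, selectable via `eta_exponent` (the two differ by
#' ~10% at body temperature; see the methods vignette).
#'
#' @param v_m Molar volume in cm^3/mol, positive.
#' @param eta Water viscosity in cP, positive.
#' @param eta_exponent Exponent on viscosity; default 1.4.
#' @return D0 in cm^2/s.
#' @examples
#' free_diffusivity(9740, water_viscosity(310.15))  # ~1.0e-6 cm^2/s
#' @export
free_diffusivity <- function(v_m, eta, eta_exponent = 1.4) {
  if (any(v_m <= 0) || any(eta <= 0))
    stop("v_m and eta must be positive", call. = FALSE)
  13.26e-5 / (eta^eta_exponent * v_m^0.589)
}

#' Effective diffusivity in a membrane
#'
#' Deff = Kdiff * D0: the free-solution diffusivity reduced by the membrane's
#' diffusional hindrance. `infer_d0()` is the exact inverse, recovering D0
#' from a measured or published Deff and the hindrance of the membrane it was
#' measured in; the pair round-trips to machine precision and is the basis of
#' cross-membrane predictions.
#'
#' @param d0 Free diffusivity in cm^2/s, positive.
#' @param k_diff Hindrance factor in (0, 1].
#' @param hindrance Optional `HindranceResult`-style provenance (list with
#'   `lam`, `formula`) recorded in the result.
#' @param v_m,eta,T_K Optional provenance of D0, recorded in the result.
#' @return `effective_diffusivity()`: an object of class `diffusivity_result`
#'   with fields `d0_cm2_s`, `k_diff`, `d_eff_cm2_s` and provenance.
#'   `infer_d0()`: D0 in cm^2/s (bare numeric).
#' @examples
#' effective_diffusivity(9.812e-7, renkin_hindrance(0.204))
#' infer_d0(15e-10, open_area_hindrance(0.0545))
#' @export
effective_diffusivity <- function(d0, k_diff, hindrance = NULL,
                                  v_m = NA_real_, eta = NA_real_,
                                  T_K = NA_real_) {
  if (any(d0 <= 0)) stop("d0 must be positive", call. = FALSE)
  if (any(k_diff <= 0) || any(k_diff > 1))
    stop("k_diff must be in (0, 1]", call. = FALSE)
  structure(list(d0_cm2_s = d0, k_diff = k_diff, d_eff_cm2_s = k_diff * d0,
                 hindrance = hindrance, v_m_cm3_mol = v_m, eta_cP = eta,
                 T_K = T_K),
            class = "diffusivity_result")
}

#' @rdname effective_diffusivity
#' @param d_eff Effective diffusivity in cm^2/s.
#' @export
infer_d0 <- function(d_eff, k_diff) {
  if (any(k_diff <= 0)) stop("k_diff must be positive", call. = FALSE)
  d_eff / k_diff
}

#' @export
print.diffusivity_result <- function(x, ...) {
  cat("<diffusivity_result>\n")
  cat(sprintf("  D0    = %.4g cm^2/s\n", x$d0_cm2_s))
  cat(sprintf("  Kdiff = %.4g%s\n", x$k_diff,
              if (!is.null(x$hindrance))
                sprintf("  (%s%s)", x$hindrance$formula,
                        if (!is.null(x$hindrance$lam) && !is.na(x$hindrance$lam))
                          sprintf(", lambda = %.4g", x$hindrance$lam) else "")
              else ""))
  cat(sprintf("  Deff  = %.4g cm^2/s\n", x$d_eff_cm2_s))
  invisible(x)
}

#' Specify a membrane
#'
#' A `membrane_spec` holds the geometry and transport coefficients of one
#' membrane. Two geometries are supported: `"cylindrical-nanopore"` (a
#' nanofabricated sheet of straight cylindrical pores; requires the pore
#' radius `b_nm`) and `"open-area-wall"` (a hollow-fiber wall characterised
#' by its open-area fraction `epsilon`). Exactly the geometry-appropriate one
#' of `b_nm`/`epsilon` must be given.
#'
#' @param label Short name for reports.
#' @param geometry `"cylindrical-nanopore"` or `"open-area-wall"`.
#' @param b_nm Pore radius in nm (nanopore geometry).
#' @param epsilon Open-area fraction in (0, 1] (open-area geometry).
#' @param x_m Membrane thickness in m, positive.
#' @param A_m2 Total membrane area in m^2, positive.
#' @param S Sieving coefficient in (0, 1]; default 1.
#' @param K_conv Convective hindrance coefficient; default 1.
#' @param L_p Hydraulic permeability in m/(s Pa); default `NA` (unset).
#' @param Omega Solute-coupling coefficient; default `NA` (unset).
#' @return Object of class `membrane_spec`.
#' @seealso [nanofab_membrane()], [highflux_membrane()], [read_membrane()],
#'   [membrane_kdiff()]
#' @export
membrane_spec <- function(label,
                          geometry = c("cylindrical-nanopore", "open-area-wall"),
                          b_nm = NA_real_, epsilon = NA_real_,
                          x_m, A_m2 = 1, S = 1, K_conv = 1,
                          L_p = NA_real_, Omega = NA_real_) {
  geometry <- match.arg(geometry)
  if (geometry == "cylindrical-nanopore") {
    if (is.na(b_nm) || b_nm <= 0)
      stop("cylindrical-nanopore geometry requires a positive pore radius b_nm",
           call. = FALSE)
    if (!is.na(epsilon))
      stop("epsilon is not a parameter of the nanopore geometry", call. = FALSE)
  } else {
    if (is.na(epsilon) || epsilon <= 0 || epsilon > 1)
      stop("open-area-wall geometry requires epsilon in (0, 1]", call. = FALSE)
    if (!is.na(b_nm))
      stop("b_nm is not a parameter of the open-area geometry", call. = FALSE)
  }
  if (x_m <= 0 || A_m2 <= 0) stop("x_m and A_m2 must be positive", call. = FALSE)
  if (S <= 0 || S > 1) stop("S must be in (0, 1]", call. = FALSE)
  structure(list(label = label, geometry = geometry, b_nm = b_nm,
                 epsilon = epsilon, x_m = x_m, A_m2 = A_m2, S = S,
                 K_conv = K_conv, L_p = L_p, Omega = Omega),
            class = "membrane_spec")
}

#' @export
print.membrane_spec <- function(x, ...) {
  cat(sprintf("<membrane_spec> %s [%s]\n", x$label, x$geometry))
  if (x$geometry == "cylindrical-nanopore")
    cat(sprintf("  pore radius b = %g nm\n", x$b_nm))
  else
    cat(sprintf("  open area epsilon = %g\n", x$epsilon))
  cat(sprintf("  thickness x = %g um, area A = %g m^2, S = %g, Kconv = %g\n",
              x$x_m * 1e6, x$A_m2, x$S, x$K_conv))
  if (!is.na(x$L_p) || !is.na(x$Omega))
    cat(sprintf("  Lp = %g m/(s Pa), Omega = %g\n", x$L_p, x$Omega))
  invisible(x)
}

#' Diffusional hindrance of a membrane for a given solute
#'
#' Dispatches on the membrane geometry: Renkin polynomial at
#' lambda = (d_max/2)/b for cylindrical nanopores, open-area formula for a
#' hollow-fiber wall (solute-size independent).
#'
#' @param membrane A [membrane_spec()].
#' @param d_max_nm Solute maximal dimension in nm (required for nanopore
#'   geometry).
#' @param lambda_mode Passed to [lambda_ratio()].
#' @return List with `k_diff`, `lam` (NA for open-area), `formula`.
#' @examples
#' membrane_kdiff(nanofab_membrane(), d_max_nm = 4.08)
#' membrane_kdiff(highflux_membrane())
#' @export
membrane_kdiff <- function(membrane, d_max_nm = NULL,
                           lambda_mode = c("radius", "literal")) {
  stopifnot(inherits(membrane, "membrane_spec"))
  lambda_mode <- match.arg(lambda_mode)
  if (membrane$geometry == "cylindrical-nanopore") {
    if (is.null(d_max_nm))
      stop("nanopore hindrance needs the solute dimension d_max_nm",
           call. = FALSE)
    lam <- lambda_ratio(d_max_nm, membrane$b_nm, mode = lambda_mode)
    list(k_diff = renkin_hindrance(lam), lam = lam, formula = "renkin")
  } else {
    list(k_diff = open_area_hindrance(membrane$epsilon), lam = NA_real_,
         formula = "open-area")
  }
}

#' Bundled membrane specifications
#'
#' `nanofab_membrane()`: the reference nanofabricated design — straight
#' cylindrical pores of radius 10 nm through a 1 micron thick sheet of 1 m^2
#' area, sieving coefficient 1. `highflux_membrane()`: the hollow-fiber
#' high-flux hemodialyzer wall — 5.45% open area on the blood-side surface,
#' 50 micron wall thickness.
#'
#' @param x_m Thickness override in m.
#' @param A_m2 Area override in m^2.
#' @return A [membrane_spec()].
#' @export
nanofab_membrane <- function(x_m = 1e-6, A_m2 = 1) {
  membrane_spec("nanofab_1um", "cylindrical-nanopore", b_nm = 10,
                x_m = x_m, A_m2 = A_m2, S = 1)
}

#' @rdname nanofab_membrane
#' @export
highflux_membrane <- function(x_m = 50e-6, A_m2 = 1) {
  membrane_spec("highflux_fiber", "open-area-wall", epsilon = 0.0545,
                x_m = x_m, A_m2 = A_m2, S = 1)
}

#' Read a membrane specification from a key-value file
#'
#' Plain-text format, one `key = value` pair per line, `#` comments allowed.
#' Recognised keys: `label`, `geometry`, `b_nm`, `epsilon`, `x_m`, `A_m2`,
#' `S`, `K_conv`, `L_p`, `Omega`. Two such files ship with the package under
#' `extdata/membranes/`.
#'
#' @param path Path to the file.
#' @return A [membrane_spec()].
#' @examples
#' read_membrane(system.file("extdata", "membranes", "nanofab_1um.cfg",
#'                           package = "memflux"))
#' @export
read_membrane <- function(path) {
  kv <- read_keyvalue(path)
  num <- function(k, default = NA_real_)
    if (!is.null(kv[[k]])) as.numeric(kv[[k]]) else default
  if (is.null(kv$geometry)) stop("membrane file lacks 'geometry'", call. = FALSE)
  membrane_spec(label = kv$label %||% tools::file_path_sans_ext(basename(path)),
                geometry = kv$geometry,
                b_nm = num("b_nm"), epsilon = num("epsilon"),
                x_m = num("x_m"), A_m2 = num("A_m2", 1), S = num("S", 1),
                K_conv = num("K_conv", 1), L_p = num("L_p"),
                Omega = num("Omega"))
}

# parse "key = value" lines into a named list of strings
read_keyvalue <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  bad <- !grepl("=", lines)
  if (any(bad))
    stop("malformed key-value line: '", lines[which(bad)[1]], "'",
         call. = FALSE)
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  stats::setNames(as.list(vals), keys)
}
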