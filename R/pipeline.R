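#' Write a report table as TSV with a commented metadata header
#'
#' All pipeline reports are plain TSV preceded by `# key: value` comment
#' lines recording constants, conventions and flag states. Numeric columns
#' are rendered with a fixed explicit format so outputs are byte-stable
#' across platforms.
#'
#' @param df Data.frame to write.
#' @param path Output path.
#' @param meta Named list/character of metadata to record in the header.
#' @param digits Significant digits for numeric columns (fixed scientific
#'   format); default 6.
#' @return `path`, invisibly.
#' @export
write_report <- function(df, path, meta = list(), digits = 6) {
  fmt <- paste0("%.", digits - 1, "e")
  out <- df
  for (j in seq_along(out))
    if (is.numeric(out[[j]]))
      out[[j]] <- ifelse(is.na(out[[j]]), "NA", sprintf(fmt, out[[j]]))
  con <- file(path, open = "wb")  # binary: identical line endings everywhere
  on.exit(close(con))
  hdr <- c(sprintf("# generated by memflux %s",
                   as.character(utils::packageVersion("memflux"))),
           "# sign convention: positive flux = blood to dialysate",
           sprintf("# %s: %s", names(meta), vapply(meta, as.character,
                                                   character(1L))))
  writeLines(hdr, con, sep = "\n")
  writeLines(paste(names(out), collapse = "\t"), con, sep = "\n")
  writeLines(do.call(paste, c(unname(out), sep = "\t")), con, sep = "\n")
  invisible(path)
}

#' Read a pipeline run configuration
#'
#' Plain-text `key = value` file (same dialect as [read_membrane()]).
#' Recognised keys: `catalog` (path or `builtin`), `membrane_a`,
#' `membrane_b` (paths or `nanofab_1um` / `highflux_fiber`), `toxins`
#' (comma-separated names; default all with concentrations), `deff_reference`
#' (path or `builtin` for measured Deff under membrane A), `T_K`, `pH_blood`,
#' `pH_dialysate`, `delta_V` or `sweep_dv` (`from:to:step` in volts),
#' `x_override_m`, `seed`, `eta_exponent`, `lambda_mode`,
#' `double_hindrance`, `out_dir`.
#'
#' @param path Path to the configuration file.
#' @return Named list of class `run_config`.
#' @export
read_config <- function(path) {
  kv <- read_keyvalue(path)
  structure(kv, class = "run_config")
}

.resolve_membrane <- function(spec) {
  if (is.null(spec)) return(NULL)
  if (spec == "nanofab_1um") return(nanofab_membrane())
  if (spec == "highflux_fiber") return(highflux_membrane())
  read_membrane(spec)
}

#' Run the end-to-end reporting pipeline
#'
#' Ties the stages together: structure files (optional) are measured into a
#' dimensions report; the toxin panel and two membranes produce an effective-
#' diffusivity comparison with a ratio column; and, when a potential sweep is
#' configured, one sweep table per toxin. Reports are written with
#' [write_report()] into `out_dir`; a run is fully determined by its
#' configuration and inputs (byte-identical on re-run).
#'
#' @param config A `run_config` from [read_config()], or a named list with
#'   the same keys.
#' @param out_dir Output directory; overrides `config$out_dir`; default a
#'   fresh temporary directory.
#' @param structures Optional character vector of PDB paths for the
#'   dimensions report.
#' @return Named list of paths written (`dimensions`, `comparison`,
#'   `sweeps`), class `memflux_run`.
#' @examples
#' run <- run_pipeline(list(catalog = "builtin", membrane_a = "highflux_fiber",
#'                          membrane_b = "nanofab_1um",
#'                          deff_reference = "builtin"))
#' read.delim(run$comparison, comment.char = "#")
#' @export
run_pipeline <- function(config, out_dir = NULL, structures = NULL) {
  cfg <- as.list(config)
  out_dir <- out_dir %||% cfg$out_dir %||% tempfile("memflux_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cat_path <- cfg$catalog %||% "builtin"
  catalog <- if (identical(cat_path, "builtin")) toxin_catalog()
             else toxin_catalog(cat_path)
  if (!is.null(cfg$toxins)) {
    want <- trimws(strsplit(cfg$toxins, ",")[[1L]])
    missing <- setdiff(want, names(catalog))
    if (length(missing))
      stop("config names unknown toxins: ", paste(missing, collapse = ", "),
           call. = FALSE)
    catalog <- structure(catalog[want], class = "toxin_catalog")
  }
  if (length(catalog) == 0L)
    stop("configuration selects an empty toxin list", call. = FALSE)

  membrane_a <- .resolve_membrane(cfg$membrane_a %||% "highflux_fiber")
  membrane_b <- .resolve_membrane(cfg$membrane_b %||% "nanofab_1um")
  if (!is.null(cfg$x_override_m)) membrane_b$x_m <- as.numeric(cfg$x_override_m)
  lambda_mode <- cfg$lambda_mode %||% "radius"
  eta_exponent <- as.numeric(cfg$eta_exponent %||% 1.4)
  double_hindrance <- as.logical(cfg$double_hindrance %||% TRUE)
  T_K <- as.numeric(cfg$T_K %||% 310.15)

  meta_common <- list(lambda_mode = lambda_mode, eta_exponent = eta_exponent,
                      double_hindrance = double_hindrance, T_K = T_K,
                      F_C_per_mol = 96485, R_J_per_mol_K = 8.314)
  paths <- list()

  if (!is.null(structures)) {
    dims <- do.call(rbind, lapply(structures, function(p) {
      s <- read_structure(p)
      d <- max_dimension(s)
      data.frame(accession = tools::file_path_sans_ext(basename(p)),
                 n_atoms = d$n_atoms, d_max_A = d$d_max_A,
                 d_max_nm = d$d_max_nm,
                 endpoint_i = d$endpoints[1L], endpoint_j = d$endpoints[2L])
    }))
    paths$dimensions <- write_report(dims, file.path(out_dir, "dimensions.tsv"),
                                     meta = c(list(report = "dimensions"),
                                              meta_common))
  }

  deff_ref <- NULL
  ref_spec <- cfg$deff_reference
  if (!is.null(ref_spec)) {
    ref_path <- if (identical(ref_spec, "builtin"))
      system.file("extdata", "highflux_deff_reference.tsv",
                  package = "memflux", mustWork = TRUE) else ref_spec
    rt <- utils::read.delim(ref_path, stringsAsFactors = FALSE)
    deff_ref <- stats::setNames(rt$d_eff_highflux_cm2_s, rt$toxin)
    catalog <- structure(catalog[names(catalog) %in% names(deff_ref)],
                         class = "toxin_catalog")
  }
  cmp <- compare_membranes(catalog, membrane_a, membrane_b,
                           d_eff_a_cm2_s = deff_ref,
                           lambda_mode = lambda_mode,
                           eta_exponent = eta_exponent, T_K = T_K)
  paths$comparison <- write_report(
    cmp[, setdiff(names(cmp), "d0_source")],
    file.path(out_dir, "deff_comparison.tsv"),
    meta = c(list(report = "effective diffusivity comparison (cm^2/s)",
                  membrane_a = membrane_a$label, membrane_b = membrane_b$label,
                  d0_source = unique(cmp$d0_source)), meta_common))

  if (!is.null(cfg$sweep_dv)) {
    parts <- as.numeric(strsplit(cfg$sweep_dv, ":")[[1L]])
    if (length(parts) != 3L || any(!is.finite(parts)))
      stop("sweep_dv must be 'from:to:step' in volts", call. = FALSE)
    grid <- seq(parts[1L], parts[2L], by = parts[3L])
    forces <- driving_forces(
      pH_blood = as.numeric(cfg$pH_blood %||% NA),
      pH_dialysate = as.numeric(cfg$pH_dialysate %||% NA), T_K = T_K)
    sweeps <- character(0)
    for (t in catalog) {
      d0 <- if (!is.null(deff_ref) && t$name %in% names(deff_ref))
        infer_d0(deff_ref[[t$name]],
                 membrane_kdiff(membrane_a, t$d_max_nm, lambda_mode)$k_diff)
      else NULL
      sw <- flux_sweep(t, membrane_b, forces, variable = "delta_V",
                       grid = grid, d0_cm2_s = d0,
                       eta_exponent = eta_exponent, lambda_mode = lambda_mode,
                       double_hindrance = double_hindrance)
      p <- file.path(out_dir, sprintf("sweep_dv_%s.tsv",
                                      gsub("[^A-Za-z0-9]+", "_", t$name)))
      write_report(as.data.frame(sw), p,
                   meta = c(list(report = "potential sweep (mol/s)",
                                 toxin = t$name, membrane = membrane_b$label,
                                 electromigration_units =
                                   "per unit valence when z unset"),
                            meta_common))
      sweeps <- c(sweeps, p)
    }
    paths$sweeps <- sweeps
  }
  structure(paths, class = "memflux_run")
}

#' @export
print.memflux_run <- function(x, ...) {
  cat("<memflux_run> reports written:\n")
  for (n in names(x)) cat(sprintf("  %-11s %s\n", n,
                                  paste(x[[n]], collapse = "\n              ")))
  invisible(x)
}
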