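#' Construct a uremic-toxin species record
#'
#' A `toxin_species` bundles everything the transport pipeline needs to know
#' about one solute: its maximal linear dimension (the point-set diameter of
#' its structure), molar mass, normal plasma concentration, and optionally a
#' signed valence. The molar concentration at the membrane, `c_molar`
#' (mol/m^3), is derived from the mass concentration and molar mass.
#'
#' @param name Toxin name, e.g. `"Endothelin"`.
#' @param pdb_id Protein Data Bank accession (4 characters, digit first), or
#'   `NA`.
#' @param d_max_nm Maximal linear dimension of the molecule in nm; must be
#'   positive.
#' @param molar_mass Molar mass in g/mol, or `NA` when unknown.
#' @param c_normal Normal plasma mass concentration (numeric value), or `NA`.
#' @param c_unit Unit of `c_normal`: one of `"ng/L"`, `"ug/L"`, `"mg/L"`,
#'   `"g/L"`.
#' @param z Signed valence (dimensionless). Defaults to `NA` (unset); flux
#'   terms that need a valence are then reported per unit valence.
#' @param molar_mass_source Free-text provenance of the molar mass value.
#'
#' @return An object of class `toxin_species` (a named list). `c_molar` is
#'   `NA` unless both `c_normal` and `molar_mass` are available.
#' @seealso [toxin_catalog()], [to_molar()]
#' @examples
#' toxin_species("Endothelin", "1EDN", 2.6, molar_mass = 2492,
#'               c_normal = 28.8, c_unit = "ng/L")
#' @export
toxin_species <- function(name, pdb_id = NA_character_, d_max_nm,
                          molar_mass = NA_real_, c_normal = NA_real_,
                          c_unit = NA_character_, z = NA_real_,
                          molar_mass_source = NA_character_) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(d_max_nm) || length(d_max_nm) != 1L || !is.finite(d_max_nm) ||
      d_max_nm <= 0)
    stop("d_max_nm must be a single positive number", call. = FALSE)
  if (!is.na(pdb_id) && !grepl("^[0-9][A-Za-z0-9]{3}$", pdb_id))
    stop("pdb_id '", pdb_id, "' is not a valid PDB accession", call. = FALSE)
  if (!is.na(molar_mass) && molar_mass <= 0)
    stop("molar_mass must be positive when set", call. = FALSE)
  c_molar <- NA_real_
  if (!is.na(c_normal) && !is.na(molar_mass)) {
    c_molar <- to_molar(c_normal, c_unit, molar_mass)
  }
  structure(list(name = name, pdb_id = pdb_id, d_max_nm = d_max_nm,
                 molar_mass = molar_mass,
                 molar_mass_source = molar_mass_source,
                 c_normal = c_normal, c_unit = c_unit,
                 c_molar = c_molar, z = z),
            class = "toxin_species")
}

#' @export
print.toxin_species <- function(x, ...) {
  cat(sprintf("<toxin_species> %s (PDB %s)\n", x$name,
              ifelse(is.na(x$pdb_id), "-", x$pdb_id)))
  cat(sprintf("  d_max      : %.3g nm\n", x$d_max_nm))
  if (!is.na(x$molar_mass))
    cat(sprintf("  molar mass : %.5g g/mol (%s)\n", x$molar_mass,
                ifelse(is.na(x$molar_mass_source), "source unrecorded",
                       x$molar_mass_source)))
  if (!is.na(x$c_normal))
    cat(sprintf("  C (plasma) : %g %s = %.4g mol/m^3\n", x$c_normal, x$c_unit,
                x$c_molar))
  cat(sprintf("  valence z  : %s\n",
              ifelse(is.na(x$z), "unset (per-valence reporting)", x$z)))
  invisible(x)
}

# multipliers taking each supported unit to g/m^3 (1 g/L = 1000 g/m^3)
.mass_conc_units <- c("ng/L" = 1e-6, "ug/L" = 1e-3, "mg/L" = 1, "g/L" = 1e3)

#' Convert a mass concentration to molar concentration
#'
#' `to_molar()` converts a mass concentration with unit to mol/m^3 given the
#' solute's molar mass; `from_molar()` is its exact inverse. Conversion is
#' exact (pure arithmetic) and the pair round-trips to machine precision.
#'
#' @param c_mass Mass concentration value(s).
#' @param unit One of `"ng/L"`, `"ug/L"`, `"mg/L"`, `"g/L"` (`"ug/L"` also
#'   accepted spelled `"µg/L"`).
#' @param molar_mass Molar mass in g/mol; must be positive.
#' @return Molar concentration in mol/m^3 (`to_molar`), or the mass
#'   concentration in `unit` (`from_molar`).
#' @examples
#' to_molar(28.8, "ng/L", 2492)    # 1.156e-08 mol/m^3
#' to_molar(1.6, "mg/L", 13343)    # 1.199e-04 mol/m^3
#' @export
to_molar <- function(c_mass, unit, molar_mass) {
  unit <- sub("µ", "u", unit)
  if (!unit %in% names(.mass_conc_units))
    stop("unknown concentration unit '", unit, "'; use one of ",
         paste(names(.mass_conc_units), collapse = ", "), call. = FALSE)
  if (!is.numeric(molar_mass) || any(molar_mass <= 0))
    stop("molar_mass must be positive", call. = FALSE)
  c_mass * .mass_conc_units[[unit]] / molar_mass
}

#' @rdname to_molar
#' @param c_molar Molar concentration in mol/m^3.
#' @export
from_molar <- function(c_molar, unit, molar_mass) {
  unit <- sub("µ", "u", unit)
  if (!unit %in% names(.mass_conc_units))
    stop("unknown concentration unit '", unit, "'", call. = FALSE)
  if (!is.numeric(molar_mass) || any(molar_mass <= 0))
    stop("molar_mass must be positive", call. = FALSE)
  c_molar * molar_mass / .mass_conc_units[[unit]]
}

#' The built-in uremic-toxin panel
#'
#' Loads the bundled panel of seven middle-molecule uremic toxins (endothelin,
#' cystatin C, retinol-binding protein, complement factor D, interleukin-6,
#' tumor necrosis factor alpha, interleukin-1 beta) with their PDB accessions
#' and maximal dimensions, plus normal plasma concentrations and referenced
#' molar masses for the three toxins carried through the full flux pipeline.
#' A user catalog in the same TSV dialect (columns `name`, `pdb_id`,
#' `d_max_nm`, `molar_mass_g_mol`, `molar_mass_source`, `c_normal_value`,
#' `c_normal_unit`) can be supplied instead.
#'
#' @param path Path to a catalog TSV; default `NULL` loads the bundled panel.
#' @return A list of [toxin_species()] objects, of class `toxin_catalog`,
#'   named by toxin.
#' @examples
#' cat7 <- toxin_catalog()
#' length(cat7)
#' cat7[["Endothelin"]]
#' @export
toxin_catalog <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "toxin_catalog.tsv", package = "memflux",
                        mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("name", "pdb_id", "d_max_nm", "molar_mass_g_mol",
            "molar_mass_source", "c_normal_value", "c_normal_unit")
  if (!all(need %in% names(tab)))
    stop("catalog file lacks required columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "), call. = FALSE)
  for (col in c("d_max_nm", "molar_mass_g_mol", "c_normal_value"))
    tab[[col]] <- as.numeric(tab[[col]])
  out <- lapply(seq_len(nrow(tab)), function(i) {
    toxin_species(tab$name[i], tab$pdb_id[i], tab$d_max_nm[i],
                  molar_mass = tab$molar_mass_g_mol[i],
                  c_normal = tab$c_normal_value[i],
                  c_unit = tab$c_normal_unit[i],
                  molar_mass_source = tab$molar_mass_source[i])
  })
  names(out) <- tab$name
  structure(out, class = "toxin_catalog")
}

#' @export
print.toxin_catalog <- function(x, ...) {
  cat(sprintf("<toxin_catalog> %d species\n", length(x)))
  for (t in x)
    cat(sprintf("  %-28s %-5s d_max %5.2f nm%s\n", t$name,
                ifelse(is.na(t$pdb_id), "-", t$pdb_id), t$d_max_nm,
                ifelse(is.na(t$c_molar), "",
                       sprintf("  C %.4g mol/m^3", t$c_molar))))
  invisible(x)
}

#' @export
as.data.frame.toxin_catalog <- function(x, ...) {
  do.call(rbind, lapply(x, function(t)
    data.frame(name = t$name, pdb_id = t$pdb_id, d_max_nm = t$d_max_nm,
               molar_mass_g_mol = t$molar_mass, c_normal = t$c_normal,
               c_unit = t$c_unit, c_molar_mol_m3 = t$c_molar, z = t$z,
               row.names = NULL)))
}

#' Printed per-toxin flux coefficients (reference only, non-normative)
#'
#' The source study prints, for a 1 micron membrane, one linear coefficient
#' per toxin for the electromigration term (per unit valence, mol/s per unit
#' potential) and one for the pH term. These coefficients depend on unstated
#' valences, molar masses and unit conventions and could not be reconstructed
#' consistently under any single convention (see the methods vignette); they
#' are therefore shipped for reference only and are never used in any
#' computation in this package. The `non_normative` column is `TRUE`
#' throughout.
#'
#' @return A data.frame with columns `toxin`, `electromigration_per_z`,
#'   `pH_coefficient`, `non_normative`.
#' @export
reference_flux_coefficients <- function() {
  data.frame(
    toxin = c("Endothelin", "Cystatin C", "Interleukin-6"),
    electromigration_per_z = c(3.49e-9, 2.58e-5, 6.79e-11),
    pH_coefficient = c(492.30e-12, 297.63e-8, 83.52e-14),
    non_normative = TRUE
  )
}
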