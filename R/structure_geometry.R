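#' Read a protein structure from PDB format
#'
#' Parses a PDB file (or literal PDB text) into a `structure_model`: a table
#' of atom coordinates plus a record of the selection applied. Parsing is done
#' by \pkg{bio3d}; a pre-validation pass first checks every ATOM/HETATM record
#' for parseable coordinate fields so malformed input is reported with its
#' line number.
#'
#' Defaults reproduce the selection used for maximal-dimension measurements:
#' first model only (NMR ensembles contribute a single frame), all chains of
#' the deposited asymmetric unit, waters always excluded, hydrogens and
#' heteroatoms excluded unless requested, and alternate locations resolved to
#' the highest-occupancy conformer.
#'
#' @param x Path to a PDB file, or a character string containing PDB records
#'   (detected by the presence of a newline or an ATOM/HETATM/MODEL prefix).
#' @param chains Optional character vector of chain identifiers to keep.
#' @param include_hydrogens Keep hydrogen (and deuterium) atoms? Default
#'   `FALSE`.
#' @param include_hetero Keep non-water HETATM records (ligands, ions)?
#'   Default `FALSE`: protein/nucleic ATOM records only.
#' @param model Which model of a multi-model file to use (default 1).
#'
#' @return An object of class `structure_model`: list with `atoms` (data.frame
#'   with columns `element`, `x`, `y`, `z` in Angstrom, `chain`, `occupancy`,
#'   `altloc`, `resid`, `resno`, `elety`), `model_index`, and `selection`
#'   (record of the filters applied and atom counts before/after).
#' @seealso [max_dimension()], [synthetic_structure()]
#' @examples
#' pdb <- synthetic_structure(diameter = 12, n_atoms = 20, seed = 1)
#' s <- read_structure(pdb$pdb_text)
#' nrow(s$atoms)
#' @export
read_structure <- function(x, chains = NULL, include_hydrogens = FALSE,
                           include_hetero = FALSE, model = 1L) {
  is_text <- length(x) > 1L || grepl("\n", x) ||
    grepl("^(ATOM|HETATM|MODEL|HEADER)", x)
  if (is_text) {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(if (length(x) > 1L) x else strsplit(x, "\n")[[1L]], path)
  } else {
    if (!file.exists(x)) stop("no such file: ", x, call. = FALSE)
    path <- x
  }
  .validate_pdb_lines(readLines(path, warn = FALSE))

  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE, rm.alt = FALSE)
  at <- pdb$atom
  n_total <- nrow(at)
  # coordinates of the requested model (bio3d stores models as rows of $xyz)
  n_models <- nrow(pdb$xyz)
  if (is.null(n_models) || is.na(n_models)) n_models <- 1L
  if (model < 1L || model > n_models)
    stop("model ", model, " requested but file has ", n_models, " model(s)",
         call. = FALSE)
  xyz <- matrix(pdb$xyz[model, ], ncol = 3L, byrow = TRUE)
  at$x <- xyz[, 1L]; at$y <- xyz[, 2L]; at$z <- xyz[, 3L]

  keep <- rep(TRUE, n_total)
  keep <- keep & !(at$resid %in% c("HOH", "WAT", "H2O", "DOD", "DIS"))
  if (!include_hetero) keep <- keep & at$type == "ATOM"
  if (!include_hydrogens) keep <- keep & !(toupper(at$elesy) %in% c("H", "D"))
  if (!is.null(chains)) keep <- keep & at$chain %in% chains
  at <- at[keep, , drop = FALSE]

  # altloc: keep blank altlocs; among lettered conformers of one atom keep the
  # highest occupancy (first on ties, i.e. conformer A)
  if (any(nzchar(at$alt) & !is.na(at$alt))) {
    key <- paste(at$chain, at$resno, at$insert, at$resid, at$elety)
    ord <- order(key, -replace(at$o, is.na(at$o), 1))
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(key[ord]), , drop = FALSE]
    at <- at[order(as.integer(rownames(at))), , drop = FALSE]
  }

  if (nrow(at) == 0L)
    stop("selection is empty: no atoms left after filtering", call. = FALSE)
  if (any(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z)))
    stop("non-finite coordinates in selection", call. = FALSE)

  atoms <- data.frame(element = at$elesy, x = at$x, y = at$y, z = at$z,
                      chain = at$chain, occupancy = at$o, altloc = at$alt,
                      resid = at$resid, resno = at$resno, elety = at$elety,
                      stringsAsFactors = FALSE)
  structure(list(
    atoms = atoms,
    model_index = as.integer(model),
    selection = list(chains = chains %||% "all",
                     include_hydrogens = include_hydrogens,
                     include_hetero = include_hetero,
                     waters_excluded = TRUE,
                     altloc = "highest occupancy",
                     n_atoms_file = n_total, n_atoms_kept = nrow(atoms))),
    class = "structure_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# coordinate fields of ATOM/HETATM records must parse as numbers; report the
# offending line number otherwise
.validate_pdb_lines <- function(lines) {
  rec <- grepl("^(ATOM  |HETATM)", lines)
  idx <- which(rec)
  for (i in idx) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("PDB parse error at line ", i, ": record shorter than coordinate ",
           "fields", call. = FALSE)
    coords <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                            substr(ln, 39, 46),
                                            substr(ln, 47, 54))))
    if (any(is.na(coords)))
      stop("PDB parse error at line ", i, ": unparseable coordinate field",
           call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %d atoms (model %d; %d in file)\n",
              nrow(x$atoms), x$model_index, x$selection$n_atoms_file))
  cat(sprintf("  chains: %s | hydrogens: %s | hetero: %s | waters excluded\n",
              paste(x$selection$chains, collapse = ","),
              x$selection$include_hydrogens, x$selection$include_hetero))
  invisible(x)
}

#' Maximal linear dimension of a molecule
#'
#' Computes the exact diameter of the atom point set: the maximum pairwise
#' Euclidean distance over all atoms, equivalent to rotating the molecule in
#' 3-D and recording the largest extent seen in any orientation. The
#' computation is exact all-pairs, evaluated in memory-bounded column blocks,
#' so the result equals the brute-force O(n^2) definition on every input.
#'
#' @param structure A `structure_model` (from [read_structure()] or
#'   [synthetic_structure()]) or an n x 3 numeric matrix of coordinates in
#'   Angstrom.
#' @return An object of class `dimension_result`: `d_max_A` and `d_max_nm`
#'   (the same length in Angstrom and nm), `endpoints` (indices of the two
#'   atoms realizing the diameter), `n_atoms`.
#' @examples
#' max_dimension(rbind(c(0, 0, 0), c(0, 0, 10)))  # 10 A
#' @export
max_dimension <- function(structure) {
  xyz <- if (inherits(structure, "structure_model"))
    as.matrix(structure$atoms[, c("x", "y", "z")])
  else as.matrix(structure)
  if (!is.numeric(xyz) || ncol(xyz) != 3L)
    stop("need an n x 3 numeric coordinate matrix", call. = FALSE)
  n <- nrow(xyz)
  if (n < 2L) stop("at least 2 atoms required", call. = FALSE)
  if (any(!is.finite(xyz))) stop("non-finite coordinates", call. = FALSE)

  sq <- rowSums(xyz^2)
  best <- -1; bi <- 1L; bj <- 2L
  block <- 512L
  for (s in seq(1L, n - 1L, by = block)) {
    e <- min(s + block - 1L, n - 1L)
    rows <- s:e
    # squared distances from rows s..e to all later points
    cross <- tcrossprod(xyz[rows, , drop = FALSE], xyz)   # |rows| x n
    d2 <- outer(sq[rows], sq, "+") - 2 * cross
    # mask j <= i so each pair is considered once
    jm <- matrix(rep(seq_len(n), each = length(rows)), nrow = length(rows))
    d2[jm <= rows] <- -Inf
    m <- which.max(d2)
    if (d2[m] > best) {
      best <- d2[m]
      bi <- rows[(m - 1L) %% length(rows) + 1L]
      bj <- (m - 1L) %/% length(rows) + 1L
    }
  }
  d <- sqrt(max(best, 0))
  structure(list(d_max_A = d, d_max_nm = d / 10,
                 endpoints = c(bi, bj), n_atoms = n),
            class = "dimension_result")
}

#' @export
print.dimension_result <- function(x, ...) {
  cat(sprintf("<dimension_result> d_max = %.3f A (%.4f nm) over %d atoms; ",
              x$d_max_A, x$d_max_nm, x$n_atoms))
  cat(sprintf("endpoints %d--%d\n", x$endpoints[1], x$endpoints[2]))
  invisible(x)
}

#' Estimate molar volume from molar mass
#'
#' The diffusivity correlation needs a molar volume V_M (cm^3/mol). For
#' proteins this is well approximated by molar mass times the partial specific
#' volume, which is remarkably constant across globular proteins
#' (0.70-0.75 cm^3/g; 0.73 cm^3/g is the conventional default).
#'
#' @param molar_mass Molar mass in g/mol, positive.
#' @param partial_specific_volume Partial specific volume in cm^3/g, positive;
#'   default 0.73.
#' @return Molar volume in cm^3/mol.
#' @examples
#' estimate_molar_volume(13343)          # cystatin C, ~9740 cm^3/mol
#' @export
estimate_molar_volume <- function(molar_mass, partial_specific_volume = 0.73) {
  if (any(molar_mass <= 0) || any(partial_specific_volume <= 0))
    stop("molar mass and partial specific volume must be positive",
         call. = FALSE)
  molar_mass * partial_specific_volume
}

#' Fetch PDB entries (network convenience)
#'
#' Thin wrapper around [bio3d::get.pdb()] downloading one or more entries into
#' a directory and returning the file paths. Purely a convenience for
#' interactive use; nothing in the package requires network access.
#'
#' @param ids Character vector of PDB accessions.
#' @param dir Destination directory (created if needed).
#' @return Character vector of file paths (invisibly from bio3d).
#' @export
fetch_pdb <- function(ids, dir = tempdir()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bio3d::get.pdb(ids, path = dir, verbose = FALSE)
}
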