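# Physicochemical profiling of predicted peptides: the eight properties used
# to screen anticancer/antimicrobial candidates, computed from published
# residue scales (recorded in `physchem_scales()`).

# Kyte & Doolittle (1982) hydropathy
KD_HYDROPATHY <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

# Average (not monoisotopic) free amino-acid masses, Da; peptide bonds
# subtract one water per bond.
AA_MASS <- c(
  A = 89.0932, C = 121.1582, D = 133.1027, E = 147.1293, F = 165.1891,
  G = 75.0666, H = 155.1546, I = 131.1729, K = 146.1876, L = 131.1729,
  M = 149.2113, N = 132.1179, P = 115.1305, Q = 146.1445, R = 174.2010,
  S = 105.0926, T = 119.1192, V = 117.1463, W = 204.2252, Y = 181.1885
)
WATER_MASS <- 18.0153

# Boman (2003) protein-interaction scale, kcal/mol (higher = stronger
# predicted protein-binding / more hydrophilic).
BOMAN_SCALE <- c(
  L = -4.92, I = -4.92, V = -4.04, F = -2.98, M = -2.35, W = -2.33,
  A = -1.81, C = -1.28, G = -0.94, Y = 0.14, P = 0.00, T = 2.57,
  S = 3.40, H = 4.66, Q = 5.54, K = 5.55, N = 6.64, E = 6.81,
  D = 8.72, R = 14.92
)

# Guruprasad, Reddy & Pandit (1990) dipeptide instability weight values.
DIWV_ORDER <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
DIWV <- matrix(c(
  1, 44.94, -7.49, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 1,
  1, 1, 20.26, 1, 1, 1, 33.6, 1, 1, 20.26, 33.6, 1, 20.26, -6.54, 1, 1, 33.6,
  -6.54, 24.68, 1,
  1, 1, 1, 1, -6.54, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, -6.54, 20.26, -14.03, 1,
  1, 1,
  1, 44.94, 20.26, 33.6, 1, 1, -6.54, 20.26, 1, 1, 1, 1, 20.26, 20.26, 1,
  20.26, 1, 1, -14.03, 1,
  1, 1, 13.34, 1, 1, 1, 1, 1, -14.03, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1,
  33.601,
  -7.49, 1, 1, -6.54, 1, 13.34, 1, -7.49, -7.49, 1, 1, -7.49, 1, 1, 1, 1,
  -7.49, 1, 13.34, -7.49,
  1, 1, 1, 1, -9.37, -9.37, 1, 44.94, 24.68, 1, 1, 24.68, -1.88, 1, 1, 1,
  -6.54, 1, -1.88, 44.94,
  1, 1, 1, 44.94, 1, 1, 13.34, 1, -7.49, 20.26, 1, 1, -1.88, 1, 1, 1, 1,
  -7.49, 1, 1,
  1, 1, 1, 1, 1, -7.49, 1, -7.49, 1, -7.49, 33.6, 1, -6.54, 24.64, 33.6, 1,
  1, -7.49, 1, 1,
  1, 1, 1, 1, 1, 1, 1, 1, -7.49, 1, 1, 1, 20.26, 33.6, 20.26, 1, 1, 1, 24.68,
  1,
  13.34, 1, 1, 1, 1, 1, 58.28, 1, 1, 1, -1.88, 1, 44.94, -6.54, -6.54, 44.94,
  -1.88, 1, 1, 24.68,
  1, -1.88, 1, 1, -14.03, -14.03, 1, 44.94, 24.68, 1, 1, 1, -1.88, -6.54, 1,
  1, -7.49, 1, -9.37, 1,
  20.26, -6.54, -6.54, 18.38, 20.26, 1, 1, 1, 1, 1, -6.54, 1, 20.26, 20.26,
  -6.54, 20.26, 1, 20.26, -1.88, 1,
  1, -6.54, 20.26, 20.26, -6.54, 1, 1, 1, 1, 1, 1, 1, 20.26, 20.26, 1, 44.94,
  1, -6.54, 1, -6.54,
  1, 1, 1, 1, 1, -7.49, 20.26, 1, 1, 1, 1, 13.34, 20.26, 20.26, 58.28, 44.94,
  1, 1, 58.28, -6.54,
  1, 33.6, 1, 20.26, 1, 1, 1, 1, 1, 1, 1, 1, 44.94, 20.26, 20.26, 20.26, 1,
  1, 1, 1,
  1, 1, 1, 20.26, 13.34, -7.49, 1, 1, 1, 1, 1, -14.03, 1, -6.54, 1, 1, 1, 1,
  -14.03, 1,
  1, 1, -14.03, 1, 1, -7.49, 1, 1, -1.88, 1, 1, 1, 20.26, 1, 1, 1, -7.49, 1,
  1, -6.54,
  -14.03, 1, 1, 1, 1, -9.37, 24.68, 1, 1, 13.34, 24.68, 13.34, 1, 1, 1, 1,
  -14.03, -7.49, 1, 1,
  24.68, 1, 24.68, -6.54, 1, -7.49, 13.34, 1, 1, 1, 44.94, 1, 13.34, 1,
  -15.91, 1, -7.49, 1, -9.37, 13.34
), nrow = 20L, byrow = TRUE, dimnames = list(DIWV_ORDER, DIWV_ORDER))

# Ionizable-group pKa sets for charge and pI.
PKA_SETS <- list(
  EMBOSS = c(Nterm = 8.6, Cterm = 3.6, K = 10.8, R = 12.5, H = 6.5,
             D = 3.9, E = 4.1, C = 8.5, Y = 10.1),
  Bjellqvist = c(Nterm = 7.5, Cterm = 3.55, K = 10.0, R = 12.0, H = 5.98,
                 D = 4.05, E = 4.45, C = 9.0, Y = 10.0)
)

#' Residue scales used by the physicochemical properties
#'
#' @return Named list of the Kyte-Doolittle hydropathy scale, average residue
#'   masses, Boman interaction scale, Guruprasad dipeptide instability
#'   weights and the available pKa sets, as used by the property functions.
#' @export
physchem_scales <- function() {
  list(hydropathy = KD_HYDROPATHY, mass = AA_MASS, boman = BOMAN_SCALE,
       diwv = DIWV, pka = PKA_SETS, water = WATER_MASS)
}

pep_chars <- function(peptide, what, allow_x = FALSE) {
  chars <- strsplit(peptide, "", fixed = TRUE)[[1]]
  if (length(chars) == 0L) stop(what, " undefined for an empty peptide")
  bad <- which(!chars %in% names(KD_HYDROPATHY))
  if (!allow_x && length(bad) > 0L) {
    stop(what, " undefined for non-standard residues at position(s) ",
         paste(bad, collapse = ", "))
  }
  chars
}

#' GRAVY: grand average of hydropathy
#'
#' Arithmetic mean of the per-residue Kyte-Doolittle hydropathy values;
#' positive values indicate hydrophobic peptides.
#'
#' @param peptide Peptide string over the 20 standard residues.
#' @return Scalar (dimensionless).
#' @export
gravy <- function(peptide) {
  mean(KD_HYDROPATHY[pep_chars(peptide, "GRAVY")])
}

#' Molecular weight (average masses)
#'
#' Sum of average residue masses minus one water per peptide bond.
#'
#' @inheritParams gravy
#' @return Mass in Da.
#' @export
molecular_weight <- function(peptide) {
  chars <- pep_chars(peptide, "molecular weight")
  sum(AA_MASS[chars]) - (length(chars) - 1L) * WATER_MASS
}

#' Aromaticity and tryptophan content
#'
#' Aromaticity is the fraction of F/W/Y residues; tryptophan content is the
#' fraction of W.
#'
#' @inheritParams gravy
#' @return Fraction in \[0, 1\].
#' @export
aromaticity <- function(peptide) {
  chars <- pep_chars(peptide, "aromaticity", allow_x = TRUE)
  mean(chars %in% c("F", "W", "Y"))
}

#' @rdname aromaticity
#' @export
trp_content <- function(peptide) {
  chars <- pep_chars(peptide, "tryptophan content", allow_x = TRUE)
  mean(chars == "W")
}

#' Guruprasad instability index
#'
#' `(10/L) * sum` of dipeptide instability weight values over consecutive
#' residue pairs; values above 40 predict in-vitro instability.
#'
#' @inheritParams gravy
#' @return Scalar (dimensionless).
#' @export
instability_index <- function(peptide) {
  chars <- pep_chars(peptide, "instability index")
  n <- length(chars)
  if (n < 2L) stop("instability index needs at least 2 residues")
  (10 / n) * sum(DIWV[cbind(chars[-n], chars[-1L])])
}

#' Net charge at a given pH
#'
#' Henderson-Hasselbalch sum over the N-terminus, C-terminus and the
#' ionizable side chains (D, E, C, Y, H, K, R) under the chosen pKa set.
#'
#' @inheritParams gravy
#' @param pH pH at which to evaluate the charge.
#' @param pka_set `"EMBOSS"` (default) or `"Bjellqvist"`.
#' @return Net charge in elementary charges.
#' @export
net_charge <- function(peptide, pH = 7.0, pka_set = "EMBOSS") {
  chars <- pep_chars(peptide, "net charge")
  pka <- PKA_SETS[[match.arg(pka_set, names(PKA_SETS))]]
  counts <- table(factor(chars, levels = names(KD_HYDROPATHY)))
  pos_groups <- c(Nterm = 1, K = unname(counts["K"]),
                  R = unname(counts["R"]), H = unname(counts["H"]))
  neg_groups <- c(Cterm = 1, D = unname(counts["D"]),
                  E = unname(counts["E"]), C = unname(counts["C"]),
                  Y = unname(counts["Y"]))
  pos <- sum(pos_groups / (1 + 10^(pH - pka[names(pos_groups)])))
  neg <- sum(neg_groups / (1 + 10^(pka[names(neg_groups)] - pH)))
  pos - neg
}

#' Isoelectric point
#'
#' The pH at which [net_charge()] is zero, found by bisection on (0, 14) to
#' an absolute charge below `tol`.
#'
#' @inheritParams net_charge
#' @param tol Convergence tolerance on |charge| (default 1e-4).
#' @param max_iter Maximum bisection iterations (default 200).
#' @return pI in pH units.
#' @export
isoelectric_point <- function(peptide, pka_set = "EMBOSS", tol = 1e-4,
                              max_iter = 200L) {
  lo <- 0; hi <- 14
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    q <- net_charge(peptide, mid, pka_set)
    if (abs(q) < tol) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
  stop("pI bisection did not converge in ", max_iter, " iterations")
}

#' Boman interaction index
#'
#' Mean of the per-residue Boman (2003) interaction values; high values
#' suggest strong protein-binding potential.
#'
#' @inheritParams gravy
#' @return Index in kcal/mol.
#' @export
boman_index <- function(peptide) {
  mean(BOMAN_SCALE[pep_chars(peptide, "Boman index")])
}

#' Profile peptides across the eight physicochemical properties
#'
#' Computes GRAVY, molecular weight, aromaticity, instability index,
#' isoelectric point, net charge at pH 7, Boman index and tryptophan content
#' for each peptide. Peptides containing `X` (for which the table-based
#' properties are undefined) are dropped with a warning when
#' `drop_x = TRUE`, otherwise they are an error.
#'
#' @param peptides Tibble with `id` and `sequence` (or a character vector).
#' @param pka_set pKa set for charge and pI.
#' @param drop_x Drop peptides containing non-standard residues (default
#'   `TRUE`).
#' @return A tibble of class `property_matrix` with one row per peptide and
#'   one column per property (raw values).
#' @export
profile_peptides <- function(peptides, pka_set = "EMBOSS", drop_x = TRUE) {
  if (is.character(peptides)) {
    peptides <- tibble::tibble(id = paste0("pep", seq_along(peptides)),
                               sequence = peptides)
  }
  stopifnot(nrow(peptides) >= 1L)
  has_x <- grepl("[^ACDEFGHIKLMNPQRSTVWY]", peptides$sequence)
  if (any(has_x)) {
    if (!drop_x) {
      stop("peptide(s) with non-standard residues: ",
           paste(peptides$id[has_x], collapse = ", "))
    }
    warning(sum(has_x), " peptide(s) with non-standard residues dropped")
    peptides <- peptides[!has_x, , drop = FALSE]
    if (nrow(peptides) == 0L) stop("no profilable peptides left")
  }
  out <- tibble::tibble(
    id = peptides$id,
    gravy = vapply(peptides$sequence, gravy, numeric(1), USE.NAMES = FALSE),
    mol_weight = vapply(peptides$sequence, molecular_weight, numeric(1),
                        USE.NAMES = FALSE),
    aromaticity = vapply(peptides$sequence, aromaticity, numeric(1),
                         USE.NAMES = FALSE),
    instability = vapply(peptides$sequence, instability_index, numeric(1),
                         USE.NAMES = FALSE),
    pI = vapply(peptides$sequence, isoelectric_point, numeric(1),
                pka_set = pka_set, USE.NAMES = FALSE),
    net_charge_pH7 = vapply(peptides$sequence, net_charge, numeric(1),
                            pH = 7.0, pka_set = pka_set, USE.NAMES = FALSE),
    boman = vapply(peptides$sequence, boman_index, numeric(1),
                   USE.NAMES = FALSE),
    w_content = vapply(peptides$sequence, trp_content, numeric(1),
                       USE.NAMES = FALSE)
  )
  class(out) <- c("property_matrix", class(out))
  out
}

#' Min-max normalize a property matrix
#'
#' Each property column is rescaled to \[0, 1\]; a constant column maps to 0
#' with a warning. The per-column minima and maxima are stored as attributes
#' `mins`/`maxs` so raw values are recoverable.
#'
#' @param matrix A `property_matrix` from [profile_peptides()].
#' @return The normalized `property_matrix` (same shape), with attributes.
#' @export
normalize_properties <- function(matrix) {
  cols <- setdiff(names(matrix), "id")
  mins <- vapply(matrix[cols], min, numeric(1))
  maxs <- vapply(matrix[cols], max, numeric(1))
  out <- matrix
  constant <- character()
  for (cl in cols) {
    rng <- maxs[[cl]] - mins[[cl]]
    if (rng == 0) {
      constant <- c(constant, cl)
      out[[cl]] <- rep(0, nrow(matrix))
    } else {
      out[[cl]] <- (matrix[[cl]] - mins[[cl]]) / rng
    }
  }
  if (length(constant) > 0L) {
    warning("constant propert", if (length(constant) > 1L) "ies" else "y",
            " normalized to 0: ", paste(constant, collapse = ", "))
  }
  attr(out, "mins") <- mins
  attr(out, "maxs") <- maxs
  out
}

#' Export the GRAVY / net-charge / Boman scatter table
#'
#' Raw values for the standard hydrophobicity-versus-charge view of
#' candidate peptides, with the Boman index as the third (color) dimension.
#'
#' @param matrix A `property_matrix` (raw values).
#' @param path Optional TSV output path.
#' @return Tibble with `id`, `gravy`, `net_charge_pH7`, `boman` (written to
#'   `path` when given).
#' @export
export_scatter <- function(matrix, path = NULL) {
  out <- tibble::tibble(id = matrix$id, gravy = matrix$gravy,
                        net_charge_pH7 = matrix$net_charge_pH7,
                        boman = matrix$boman)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  out
}
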