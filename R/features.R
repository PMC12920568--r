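# Feature encoding for candidate ORFs: one-hot context plus six handcrafted
# coding statistics, fused into a single model input vector.

BASES <- c("A", "C", "G", "T")
CODONS <- as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))
CODONS <- sort(CODONS)  # lexicographic AAA..TTT
DICODONS <- as.vector(outer(CODONS, CODONS, function(a, b) paste0(a, b)))
# outer() varies its first argument fastest; rebuild in row-major order so
# DICODONS[(i-1)*64 + j] == paste0(CODONS[i], CODONS[j])
DICODONS <- paste0(rep(CODONS, each = 64L), rep(CODONS, times = 64L))

#' One-hot encode a standardized ORF sequence
#'
#' @param fixed_seq String of exactly `target` symbols over A/C/G/T/N/pad.
#' @param target Expected length (default 700).
#' @return A `target` x 4 matrix of 0/1 with column order A, C, G, T. `N` and
#'   pad rows are all zero, so neither carries base signal.
#' @export
one_hot <- function(fixed_seq, target = 700L) {
  if (nchar(fixed_seq) != target) {
    stop("one_hot expects a sequence of exactly ", target, " symbols")
  }
  chars <- strsplit(fixed_seq, "", fixed = TRUE)[[1]]
  m <- matrix(0, nrow = target, ncol = 4L, dimnames = list(NULL, BASES))
  idx <- match(chars, BASES)
  ok <- !is.na(idx)
  m[cbind(which(ok), idx[ok])] <- 1
  m
}

# In-frame codon indices (1..64) for a sequence, NA for codons containing N.
codon_index <- function(nt_seq) {
  n <- nchar(nt_seq) %/% 3L
  if (n == 0L) return(integer(0))
  at <- 3L * seq_len(n) - 2L
  match(substring(nt_seq, at, at + 2L), CODONS)
}

#' Monocodon usage of an ORF
#'
#' Relative frequency of each of the 64 codons over the non-overlapping
#' in-frame codons (frame 0 of the candidate sequence). Codons containing `N`
#' are excluded from numerator and denominator.
#'
#' @param nt_seq Candidate DNA sequence (coding strand).
#' @return Named 64-vector of frequencies summing to 1, or all zeros when no
#'   complete N-free codon exists.
#' @export
monocodon_usage <- function(nt_seq) {
  idx <- codon_index(nt_seq)
  idx <- idx[!is.na(idx)]
  v <- stats::setNames(numeric(64L), CODONS)
  if (length(idx) == 0L) return(v)
  tab <- tabulate(idx, nbins = 64L)
  v[] <- tab / sum(tab)
  v
}

#' Dicodon (hexamer) usage of an ORF
#'
#' Frequency of each hexamer formed by consecutive in-frame codon pairs
#' (overlapping pairs, step of one codon). Pairs in which either codon
#' contains `N` are skipped.
#'
#' @inheritParams monocodon_usage
#' @return Named 4096-vector of frequencies summing to 1, or all zeros when
#'   fewer than two consecutive N-free codons exist.
#' @export
dicodon_usage <- function(nt_seq) {
  idx <- codon_index(nt_seq)
  v <- stats::setNames(numeric(4096L), DICODONS)
  if (length(idx) < 2L) return(v)
  a <- idx[-length(idx)]
  b <- idx[-1L]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(v)
  pair <- (a[ok] - 1L) * 64L + b[ok]
  tab <- tabulate(pair, nbins = 4096L)
  v[] <- tab / sum(tab)
  v
}

#' Train a position weight matrix for the translation-initiation region
#'
#' Builds a 30 x 4 log2-odds PWM from the upstream windows of known coding
#' starts. Windows shorter than 30 bp (clipped at fragment edges) are
#' right-aligned to the start codon. Each cell receives a pseudocount of 1
#' before normalization; the background is the base composition of
#' `background_seqs` (uniform when omitted).
#'
#' @param positive_windows Character vector of up-to-30 bp upstream windows.
#' @param background_seqs Optional character vector of sequences defining the
#'   background base frequencies.
#' @param window Window length (default 30).
#' @return An object of class `tis_pwm` with elements `weights` (window x 4,
#'   bits) and `background`.
#' @export
train_tis_pwm <- function(positive_windows, background_seqs = NULL,
                          window = 30L) {
  if (length(positive_windows) == 0L) stop("no positive windows supplied")
  counts <- matrix(1, nrow = window, ncol = 4L,
                   dimnames = list(NULL, BASES))  # pseudocount 1 per cell
  for (w in positive_windows) {
    chars <- strsplit(w, "", fixed = TRUE)[[1]]
    n <- length(chars)
    if (n == 0L) next
    if (n > window) chars <- chars[(n - window + 1L):n]
    pos <- (window - length(chars) + 1L):window  # right-aligned
    idx <- match(chars, BASES)
    ok <- !is.na(idx)
    if (any(ok)) {
      at <- cbind(pos[ok], idx[ok])
      counts[at] <- counts[at] + 1
    }
  }
  freq <- counts / rowSums(counts)
  background <- if (is.null(background_seqs)) {
    stats::setNames(rep(0.25, 4L), BASES)
  } else {
    bc <- base_composition(paste(background_seqs, collapse = ""))
    if (any(bc == 0)) bc <- (bc + 1e-4) / sum(bc + 1e-4)
    bc
  }
  structure(
    list(weights = log2(sweep(freq, 2L, background, "/")),
         background = background, window = window),
    class = "tis_pwm"
  )
}

#' Score an upstream window against a trained PWM
#'
#' Sum of per-position log2-odds for the observed bases, right-aligned to the
#' start codon as during training. `N` positions contribute 0; an empty
#' window scores 0.
#'
#' @param upstream_window Window string of length <= the PWM window.
#' @param pwm A `tis_pwm` from [train_tis_pwm()], or `NULL` (score 0, used
#'   when the TIS feature is configured off).
#' @return Scalar score in bits.
#' @export
tis_score <- function(upstream_window, pwm) {
  if (is.null(pwm)) return(0)
  chars <- strsplit(upstream_window, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n == 0L) return(0)
  window <- pwm$window
  if (n > window) chars <- chars[(n - window + 1L):n]
  pos <- (window - length(chars) + 1L):window
  idx <- match(chars, BASES)
  ok <- !is.na(idx)
  if (!any(ok)) return(0)
  sum(pwm$weights[cbind(pos[ok], idx[ok])])
}

#' Scalar length feature
#'
#' ORF length normalized by the encoder cap so it shares the unit scale of
#' the other fused entries: `min(length, cap) / cap`.
#'
#' @param length_bp ORF length in bp.
#' @param cap Normalization cap (default 700, the standardized length).
#' @export
length_feature <- function(length_bp, cap = 700L) {
  pmin(length_bp, cap) / cap
}

#' GC content over unambiguous bases
#'
#' @param nt_seq DNA string.
#' @return `(#G + #C) / (#A + #C + #G + #T)`; 0 with a warning when the
#'   sequence has no unambiguous base.
#' @export
gc_content <- function(nt_seq) {
  counts <- base_counts(nt_seq)
  tot <- sum(counts)
  if (tot == 0L) {
    warning("no unambiguous bases; GC content reported as 0")
    return(0)
  }
  (counts[["G"]] + counts[["C"]]) / tot
}

base_counts <- function(nt_seq) {
  chars <- strsplit(nt_seq, "", fixed = TRUE)[[1]]
  idx <- match(chars, BASES)
  stats::setNames(tabulate(idx[!is.na(idx)], nbins = 4L), BASES)
}

#' Base composition over unambiguous bases
#'
#' @param nt_seq DNA string.
#' @return Named 4-vector of A/C/G/T frequencies (all zeros with a warning
#'   for an all-N sequence).
#' @export
base_composition <- function(nt_seq) {
  counts <- base_counts(nt_seq)
  tot <- sum(counts)
  if (tot == 0L) {
    warning("no unambiguous bases; base composition reported as all zeros")
    return(stats::setNames(numeric(4L), BASES))
  }
  counts / tot
}

#' Fused-vector block layout
#'
#' @param target Standardized ORF length (default 700).
#' @return Tibble with `block`, `offset` (0-based start within the fused
#'   vector) and `width` for each of the seven blocks, in their fixed order.
#' @export
feature_blocks <- function(target = 700L) {
  widths <- c(one_hot = 4L * target, monocodon = 64L, dicodon = 4096L,
              tis = 1L, orf_length = 1L, gc = 1L, base_comp = 4L)
  tibble::tibble(
    block = names(widths),
    offset = cumsum(c(0L, unname(widths[-length(widths)]))),
    width = unname(widths)
  )
}

#' Fuse the one-hot matrix and handcrafted features into one vector
#'
#' Blocks are concatenated in the fixed order: flattened one-hot (row-major,
#' 4 entries per position), monocodon, dicodon, TIS score, length, GC, base
#' composition — 6,967 entries under the defaults.
#'
#' @param onehot Matrix from [one_hot()].
#' @param bundle Named list with elements `monocodon`, `dicodon`, `tis`,
#'   `orf_length`, `gc`, `base_comp`.
#' @return Numeric vector with the block layout attached as attribute
#'   `blocks`.
#' @export
fuse_features <- function(onehot, bundle) {
  needed <- c("monocodon", "dicodon", "tis", "orf_length", "gc", "base_comp")
  missing <- setdiff(needed, names(bundle))
  if (length(missing) > 0L) {
    stop("missing feature block(s): ", paste(missing, collapse = ", "))
  }
  v <- c(as.vector(t(onehot)), bundle$monocodon, bundle$dicodon,
         bundle$tis, bundle$orf_length, bundle$gc, bundle$base_comp)
  v <- unname(v)
  attr(v, "blocks") <- feature_blocks(nrow(onehot))
  v
}

#' Compute fused feature vectors for a candidate set
#'
#' Standardizes, one-hot encodes, computes the six handcrafted features and
#' fuses them, one row per candidate.
#'
#' @param candidates Candidate tibble from [scan_orfs()].
#' @param pwm Optional `tis_pwm`; when `NULL` the TIS entry is 0.
#' @param target Standardized length (default 700).
#' @return Numeric matrix (candidates x fused width) with `orf_id` rownames
#'   and the block layout as attribute `blocks`.
#' @export
featurize_orfs <- function(candidates, pwm = NULL, target = 700L) {
  if (!"fixed_seq" %in% names(candidates)) {
    candidates <- standardize_orfs(candidates, target = target)
  }
  blocks <- feature_blocks(target)
  width <- sum(blocks$width)
  x <- matrix(0, nrow = nrow(candidates), ncol = width)
  for (i in seq_len(nrow(candidates))) {
    bundle <- list(
      monocodon = monocodon_usage(candidates$nt_seq[i]),
      dicodon = dicodon_usage(candidates$nt_seq[i]),
      tis = tis_score(candidates$upstream_window[i], pwm),
      orf_length = length_feature(candidates$length[i], cap = target),
      gc = gc_content(candidates$nt_seq[i]),
      base_comp = base_composition(candidates$nt_seq[i])
    )
    x[i, ] <- fuse_features(one_hot(candidates$fixed_seq[i], target), bundle)
  }
  rownames(x) <- candidates$orf_id
  attr(x, "blocks") <- blocks
  x
}

#' Export a fused feature matrix as TSV
#'
#' One row per candidate with an `orf_id` column and one column per fused
#' entry named `<block><index>`.
#'
#' @param x Matrix from [featurize_orfs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(x, path) {
  blocks <- attr(x, "blocks")
  cols <- unlist(purrr::map2(blocks$block, blocks$width,
                             function(b, w) paste0(b, seq_len(w))))
  df <- data.frame(orf_id = rownames(x), x, check.names = FALSE)
  names(df) <- c("orf_id", cols)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
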