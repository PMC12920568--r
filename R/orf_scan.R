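# Six-frame ORF enumeration with the completeness taxonomy used for
# metagenomic fragments, plus length standardization for the encoder.

ORF_START_CODONS <- c("ATG", "CTG", "GTG", "TTG")
ORF_STOP_CODONS <- c("TAA", "TAG", "TGA")
ORF_PAD <- "."  # padding symbol; one-hot encodes to all zeros, like N

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Enumerate candidate ORFs in all six frames
#'
#' Every stop-to-stop segment in each frame of each strand is examined. By
#' default one candidate is emitted per (stop, frame, strand): the longest
#' ORF, i.e. the one beginning at the 5'-most in-frame start codon
#' (ATG/CTG/GTG/TTG). With `all_starts = TRUE` one candidate is emitted per
#' in-frame start. Fragment-edge segments lacking a start and/or stop are
#' emitted with the matching completeness class (`missing5`, `missing3`,
#' `missing_both`), the situation typical of metagenomic fragments.
#' Candidates shorter than `min_len` (stop codon included) are dropped. The
#' up-to-`upstream` bp window 5' of each candidate start is retained for the
#' translation-initiation-site score.
#'
#' @param records Tibble of genome records from [read_fasta()] (columns `id`,
#'   `sequence`), or a single record row.
#' @param min_len Minimum candidate length in bp (default 60).
#' @param upstream Length of the retained upstream window in bp (default 30).
#' @param all_starts Emit one candidate per in-frame start codon instead of
#'   only the longest ORF per stop.
#' @return Tibble with columns `orf_id`, `seq_id`, `start`, `end` (0-based
#'   half-open, forward strand), `strand`, `frame`, `completeness`, `nt_seq`
#'   (5'->3' on the coding strand), `upstream_window`, `length`.
#' @export
scan_orfs <- function(records, min_len = 60L, upstream = 30L,
                      all_starts = FALSE) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  out <- purrr::map(seq_len(nrow(records)), function(i) {
    scan_orfs_one(records$id[i], records$sequence[i],
                  min_len = min_len, upstream = upstream,
                  all_starts = all_starts)
  })
  dplyr::bind_rows(out)
}

empty_candidates <- function() {
  tibble::tibble(
    orf_id = character(), seq_id = character(),
    start = integer(), end = integer(), strand = character(),
    frame = integer(), completeness = character(),
    nt_seq = character(), upstream_window = character(), length = integer()
  )
}

scan_orfs_one <- function(seq_id, sequence, min_len, upstream, all_starts) {
  if (grepl("[^ACGTN]", sequence)) {
    stop("sequence for ", seq_id, " contains non-DNA characters")
  }
  len <- nchar(sequence)
  if (len < min_len) return(empty_candidates())
  rows <- list()
  for (strand in c("+", "-")) {
    coding <- if (strand == "+") sequence else revcomp(sequence)
    for (frame in 0:2) {
      n_codon <- (len - frame) %/% 3L
      if (n_codon < 1L) next
      at <- frame + 3L * (seq_len(n_codon) - 1L) + 1L  # 1-based codon starts
      codons <- substring(coding, at, at + 2L)
      stop_idx <- which(codons %in% ORF_STOP_CODONS)
      start_idx <- which(codons %in% ORF_START_CODONS)
      segs <- segment_candidates(stop_idx, start_idx, n_codon, all_starts)
      if (nrow(segs) == 0L) next
      # codon index range -> coding-strand 0-based half-open bp coordinates
      p1 <- frame + 3L * (segs$from - 1L)
      p2 <- frame + 3L * segs$to
      keep <- (p2 - p1) >= min_len
      if (!any(keep)) next
      p1 <- p1[keep]; p2 <- p2[keep]; compl <- segs$completeness[keep]
      if (strand == "+") {
        fwd_start <- p1; fwd_end <- p2
      } else {
        fwd_start <- len - p2; fwd_end <- len - p1
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        seq_id = seq_id,
        start = fwd_start, end = fwd_end, strand = strand,
        frame = frame, completeness = compl,
        nt_seq = substring(coding, p1 + 1L, p2),
        upstream_window = substring(coding, pmax(0L, p1 - upstream) + 1L, p1),
        length = p2 - p1
      )
    }
  }
  if (length(rows) == 0L) return(empty_candidates())
  out <- dplyr::bind_rows(rows)
  out$orf_id <- sprintf("%s:%d-%d(%s)", out$seq_id, out$start, out$end,
                        out$strand)
  dplyr::select(out, "orf_id", dplyr::everything())
}

# Candidate codon ranges [from, to] (inclusive, stop codon included when
# present) for one frame, given stop/start codon indices. Pure index
# arithmetic so the same function serves both strands.
segment_candidates <- function(stop_idx, start_idx, n_codon, all_starts) {
  from <- integer(); to <- integer(); compl <- character()
  add <- function(f, t, c) {
    from <<- c(from, f); to <<- c(to, t); compl <<- c(compl, c)
  }
  prev <- 0L
  for (s in stop_idx) {
    starts_in <- start_idx[start_idx > prev & start_idx < s]
    if (length(starts_in) > 0L) {
      use <- if (all_starts) starts_in else starts_in[1L]
      for (a in use) add(a, s, "complete")
    } else if (prev == 0L) {
      # 5' fragment edge in this reading frame, no start before first stop
      add(1L, s, "missing5")
    }
    prev <- s
  }
  # tail segment: after the last stop (or the whole frame if no stop)
  if (prev < n_codon) {
    starts_tail <- start_idx[start_idx > prev]
    if (length(starts_tail) > 0L) {
      use <- if (all_starts) starts_tail else starts_tail[1L]
      for (a in use) add(a, n_codon, "missing3")
    } else if (prev == 0L) {
      add(1L, n_codon, "missing_both")
    }
  }
  tibble::tibble(from = from, to = to, completeness = compl)
}

#' Standardize candidate sequences to a fixed encoder length
#'
#' Sequences shorter than `target` are 3'-padded with the neutral pad symbol
#' (which one-hot encodes to all zeros); longer sequences keep their 5'-most
#' `target` bp, since the start-proximal region carries the discriminative
#' translation-initiation signal.
#'
#' @param candidates Candidate tibble from [scan_orfs()].
#' @param target Fixed length in bp (default 700).
#' @return The input tibble with a `fixed_seq` column of exactly `target`
#'   symbols per row.
#' @export
standardize_orfs <- function(candidates, target = 700L) {
  candidates$fixed_seq <- vapply(candidates$nt_seq, standardize_length,
                                 character(1), target = target,
                                 USE.NAMES = FALSE)
  candidates
}

#' @rdname standardize_orfs
#' @param nt_seq A single candidate sequence.
#' @export
standardize_length <- function(nt_seq, target = 700L) {
  if (target <= 0L) stop("target length must be positive")
  n <- nchar(nt_seq)
  if (n >= target) {
    substr(nt_seq, 1L, target)
  } else {
    paste0(nt_seq, strrep(ORF_PAD, target - n))
  }
}

#' Forward-strand overlap between two interval sets, in bp
#'
#' Overlap is measured on forward-strand coordinates regardless of strand, so
#' opposite-strand candidates also compete during greedy resolution.
#'
#' @param a,b Tibbles (or one-row slices) with `seq_id`, `start`, `end`;
#'   recycled against each other row-wise.
#' @return Integer vector of overlap widths (0 when disjoint).
#' @export
overlap_bp <- function(a, b) {
  if (any(a$seq_id != b$seq_id)) {
    stop("overlap_bp requires intervals on the same seq_id")
  }
  pmax(0L, pmin(a$end, b$end) - pmax(a$start, b$start))
}
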