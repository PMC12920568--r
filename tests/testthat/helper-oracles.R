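# Independent reference implementations ("oracles") used to cross-check the
# package. These deliberately use naive position-by-position algorithms,
# not the package's vectorized segment logic.

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

oracle_revcomp <- function(seq) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(seq, "", fixed = TRUE)[[1]]]), collapse = "")
}

# Brute-force six-frame ORF enumerator: walks every codon position keeping
# explicit state, applies the start/stop sets, the completeness taxonomy and
# the length filter, and emits forward-strand half-open coordinates.
brute_force_orfs <- function(seq_id, sequence, min_len = 60L,
                             all_starts = FALSE) {
  starts_set <- c("ATG", "CTG", "GTG", "TTG")
  stops_set <- c("TAA", "TAG", "TGA")
  len <- nchar(sequence)
  out <- list()
  emit <- function(p1, p2, strand, frame, compl, coding) {
    if (p2 - p1 < min_len) return()
    if (strand == "+") {
      fs <- p1; fe <- p2
    } else {
      fs <- len - p2; fe <- len - p1
    }
    out[[length(out) + 1L]] <<- data.frame(
      seq_id = seq_id, start = fs, end = fe, strand = strand,
      frame = frame, completeness = compl,
      nt_seq = substring(coding, p1 + 1L, p2), stringsAsFactors = FALSE)
  }
  for (strand in c("+", "-")) {
    coding <- if (strand == "+") sequence else oracle_revcomp(sequence)
    for (frame in 0:2) {
      ncod <- (len - frame) %/% 3L
      if (ncod < 1L) next
      codon_starts <- frame + 3L * (seq_len(ncod) - 1L) + 1L
      codons <- substring(coding, codon_starts, codon_starts + 2L)
      codon_at <- function(i) codons[i]
      seen_stop <- FALSE
      seg_starts <- integer(0)   # codon indices of starts in open segment
      seg_begin <- 1L            # first codon index of the open segment
      any_start_anywhere <- FALSE
      for (i in seq_len(ncod)) {
        cd <- codon_at(i)
        if (cd %in% starts_set) {
          seg_starts <- c(seg_starts, i)
          any_start_anywhere <- TRUE
        }
        if (cd %in% stops_set) {
          p2 <- frame + 3L * i
          if (length(seg_starts) > 0L) {
            use <- if (all_starts) seg_starts else seg_starts[1L]
            for (a in use) emit(frame + 3L * (a - 1L), p2, strand, frame,
                                "complete", coding)
          } else if (!seen_stop) {
            emit(frame, p2, strand, frame, "missing5", coding)
          }
          seen_stop <- TRUE
          seg_starts <- integer(0)
          seg_begin <- i + 1L
        }
      }
      if (seg_begin <= ncod) {
        p2 <- frame + 3L * ncod
        if (length(seg_starts) > 0L) {
          use <- if (all_starts) seg_starts else seg_starts[1L]
          for (a in use) emit(frame + 3L * (a - 1L), p2, strand, frame,
                              "missing3", coding)
        } else if (!seen_stop) {
          emit(frame, p2, strand, frame, "missing_both", coding)
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(seq_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      frame = integer(), completeness = character(),
                      nt_seq = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

orf_key <- function(d) {
  paste(d$seq_id, d$start, d$end, d$strand, d$frame, d$completeness, d$nt_seq)
}

# O(n^2) greedy overlap resolution, re-implemented from the definition.
oracle_greedy <- function(scored, overlap_threshold = 60L, min_prob = 0.5) {
  s <- scored[scored$probability >= min_prob, , drop = FALSE]
  if (nrow(s) == 0L) return(s)
  s <- s[order(-s$probability, -(s$end - s$start), s$start), , drop = FALSE]
  kept <- s[0, , drop = FALSE]
  for (i in seq_len(nrow(s))) {
    clash <- FALSE
    for (j in seq_len(nrow(kept))) {
      if (kept$seq_id[j] == s$seq_id[i]) {
        ov <- min(kept$end[j], s$end[i]) - max(kept$start[j], s$start[i])
        if (ov > overlap_threshold) clash <- TRUE
      }
    }
    if (!clash) kept <- rbind(kept, s[i, , drop = FALSE])
  }
  kept[order(kept$seq_id, kept$start), , drop = FALSE]
}

# Direct (nested-loop) 1-D convolution: X is L x Cin, W is (k*Cin) x Cout
# with rows ordered offset-major then channel, matching the package layout.
oracle_conv1d <- function(X, W, b, k) {
  L <- nrow(X); Cin <- ncol(X); Cout <- ncol(W)
  Lout <- L - k + 1L
  Y <- matrix(0, Lout, Cout)
  for (t in seq_len(Lout)) {
    for (co in seq_len(Cout)) {
      acc <- b[co]
      for (j in seq_len(k)) {
        for (ci in seq_len(Cin)) {
          acc <- acc + X[t + j - 1L, ci] * W[(j - 1L) * Cin + ci, co]
        }
      }
      Y[t, co] <- acc
    }
  }
  Y
}

# Step-by-step single-sequence LSTM recurrence (gate order i, f, g, o).
oracle_lstm_last <- function(X, M, Wx, Wh, b) {
  H <- ncol(Wh) %/% 4L
  h <- numeric(H); cc <- numeric(H)
  sig <- function(z) 1 / (1 + exp(-z))
  for (t in seq_len(nrow(X))) {
    z <- as.vector(X[t, ] %*% Wx) + as.vector(h %*% Wh) + b
    i_ <- sig(z[1:H]); f_ <- sig(z[(H + 1):(2 * H)])
    g_ <- tanh(z[(2 * H + 1):(3 * H)]); o_ <- sig(z[(3 * H + 1):(4 * H)])
    c_new <- f_ * cc + i_ * g_
    h_new <- o_ * tanh(c_new)
    if (M[t] == 1) {
      h <- h_new; cc <- c_new
    }
  }
  h
}

# All-pairs AUC: P(score_pos > score_neg) + 0.5 * P(tie).
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# Random peptide over the 20 standard residues.
random_peptide <- function(n) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y"), n, replace = TRUE),
        collapse = "")
}
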