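# Seeded simulators: genomes with embedded codon-biased genes on both
# strands against an iid background of controllable GC, and peptide sets
# whose positive class is compositionally separable. These define the study
# conditions under which the two classifiers are trained and validated
# offline.

#' Draw a biased codon table
#'
#' Codon probabilities for gene interiors are drawn once per simulation from
#' a Dirichlet distribution centered on a fixed asymmetric reference table;
#' `strength` scales the concentration, so larger values give a sharper,
#' more reproducible bias away from the iid background. Stop codons are
#' excluded.
#'
#' @param strength Concentration multiplier (>= 0; 0 gives an exchangeable
#'   draw with no systematic bias).
#' @return Named probability vector over the 61 non-stop codons.
#' @keywords internal
biased_codon_table <- function(strength) {
  sense <- setdiff(CODONS, ORF_STOP_CODONS)
  # fixed asymmetric reference: geometric decay over the codon list, so a
  # handful of codons dominate (the codon-usage contrast the monocodon and
  # dicodon features exploit)
  ref <- 0.85^seq_along(sense)
  ref <- ref / sum(ref)
  alpha <- 1 + strength * ref * length(sense)
  g <- stats::rgamma(length(sense), shape = alpha, rate = 1)
  stats::setNames(g / sum(g), sense)
}

#' Simulate a genome with embedded codon-biased genes
#'
#' The background is iid with `P(G) + P(C) = gc_background`. Each gene is
#' ATG + interior codons drawn from the biased codon table + a uniform stop
#' codon, placed uniformly without overlap; a gene lands on the reverse
#' strand with probability `strand_prob` (inserted as its reverse
#' complement). Identical seeds give identical output.
#'
#' @param length Genome length in bp.
#' @param gc_background Background GC content in (0, 1).
#' @param n_genes Number of genes to embed.
#' @param gene_len_range Min/max gene length in bp (multiples of 3, >= 60).
#' @param codon_bias_strength Dirichlet concentration multiplier for the
#'   gene codon table (see [biased_codon_table()]).
#' @param strand_prob Probability that a gene is placed on the minus strand.
#' @param seed Integer seed.
#' @param seq_id Identifier of the simulated record.
#' @param codon_table Optional fixed codon table (named probabilities over
#'   the 61 sense codons). Supplying the table of a previous simulation
#'   yields a second genome from the same generative process — e.g. a fresh
#'   held-out genome for evaluating a model trained on the first.
#' @return List with `genome` (one-row record tibble), `truth` (annotation
#'   tibble: `seq_id`, `start`, `end`, `strand`, `gene_id`; 0-based
#'   half-open) and `codon_table`.
#' @export
simulate_genome <- function(length = 50000L, gc_background = 0.5,
                            n_genes = 40L, gene_len_range = c(300L, 900L),
                            codon_bias_strength = 50, strand_prob = 0.5,
                            seed = 1L, seq_id = "simgenome",
                            codon_table = NULL) {
  stopifnot(gene_len_range[1] >= 60L, gene_len_range %% 3L == 0,
            gc_background > 0, gc_background < 1)
  set.seed(seed)
  tab <- codon_table %||% biased_codon_table(codon_bias_strength)
  gene_lens <- 3L * sample(seq(gene_len_range[1] %/% 3L,
                               gene_len_range[2] %/% 3L), n_genes,
                           replace = TRUE)
  if (sum(gene_lens) >= length) stop("total gene footprint exceeds genome")
  # uniform non-overlapping placement by rejection
  placed_start <- integer(0); placed_end <- integer(0)
  for (i in seq_len(n_genes)) {
    ok <- FALSE
    for (attempt in seq_len(10000L)) {
      s <- sample.int(length - gene_lens[i] + 1L, 1L) - 1L
      e <- s + gene_lens[i]
      if (all(e <= placed_start | s >= placed_end)) {
        placed_start <- c(placed_start, s); placed_end <- c(placed_end, e)
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("could not place ", n_genes, " non-overlapping genes after ",
           "10,000 attempts; increase the genome length")
    }
  }
  strands <- ifelse(stats::runif(n_genes) < strand_prob, "-", "+")
  p_base <- c(A = (1 - gc_background) / 2, C = gc_background / 2,
              G = gc_background / 2, T = (1 - gc_background) / 2)
  chars <- sample(names(p_base), length, replace = TRUE, prob = p_base)
  for (i in seq_len(n_genes)) {
    n_codon <- gene_lens[i] %/% 3L
    interior <- sample(names(tab), n_codon - 2L, replace = TRUE, prob = tab)
    gene <- paste0("ATG", paste(interior, collapse = ""),
                   sample(ORF_STOP_CODONS, 1L))
    if (strands[i] == "-") gene <- revcomp(gene)
    chars[(placed_start[i] + 1L):placed_end[i]] <-
      strsplit(gene, "", fixed = TRUE)[[1]]
  }
  sequence <- paste(chars, collapse = "")
  genome <- tibble::tibble(id = seq_id, description = "simulated genome",
                           sequence = sequence, length = length)
  truth <- tibble::tibble(seq_id = seq_id, start = placed_start,
                          end = placed_end, strand = strands,
                          gene_id = paste0("gene", seq_len(n_genes)))
  truth <- truth[order(truth$start), , drop = FALSE]
  truth$gene_id <- paste0("gene", seq_len(n_genes))
  list(genome = genome, truth = truth, codon_table = tab)
}

#' Label scanned candidates against simulation truth
#'
#' Positives are candidates whose stop coordinate and strand match an
#' embedded gene; the rest are negatives. With `balance = TRUE` (default)
#' negatives are downsampled to `neg_ratio` times the positive count —
#' parity by default, matching the equal-expected-numbers construction the
#' classifiers are trained and evaluated on; a larger ratio keeps more of
#' the negative diversity (short spurious ORFs, reverse-strand shadows) in
#' the training set.
#'
#' @param candidates Candidate tibble from [scan_orfs()].
#' @param truth Truth annotations from [simulate_genome()].
#' @param balance Downsample negatives (default `TRUE`; `FALSE` keeps all).
#' @param neg_ratio Negatives kept per positive when balancing (default 1).
#' @param seed Seed for the negative downsampling.
#' @return The candidate tibble with a 0/1 `label` column.
#' @export
make_orf_dataset <- function(candidates, truth, balance = TRUE,
                             neg_ratio = 1, seed = 1L) {
  stop_key <- function(d) {
    paste(d$seq_id, ifelse(d$strand == "+", d$end, d$start), d$strand)
  }
  lab <- as.integer(stop_key(candidates) %in% stop_key(truth))
  if (sum(lab) == 0L) stop("no candidate matches a truth gene")
  candidates$label <- lab
  if (balance) {
    pos <- which(lab == 1L); neg <- which(lab == 0L)
    set.seed(seed)
    neg <- sample(neg, min(length(neg), round(neg_ratio * length(pos))))
    candidates <- candidates[sort(c(pos, neg)), , drop = FALSE]
  }
  candidates
}

#' Simulate a labeled peptide set
#'
#' Negative-class residues are iid uniform over the 20 standard amino acids;
#' positive-class residues are drawn from the enrichment-reweighted,
#' renormalized composition. The default enrichment boosts the cationic
#' (K, R) and aromatic (W, F) residues characteristic of anticancer and
#' antimicrobial peptides.
#'
#' @param n_pos,n_neg Class sizes.
#' @param len_range Min/max peptide length in residues.
#' @param enrichment Named multipliers applied to the positive-class
#'   composition.
#' @param seed Integer seed.
#' @return Tibble with `id`, `sequence`, `label` (1 = positive).
#' @export
simulate_peptides <- function(n_pos = 500L, n_neg = 500L,
                              len_range = c(15L, 40L),
                              enrichment = c(K = 4, R = 4, W = 3, F = 3),
                              seed = 702L) {
  stopifnot(n_pos > 0L, n_neg > 0L, all(enrichment > 0))
  set.seed(seed)
  aa <- names(KD_HYDROPATHY)
  w <- stats::setNames(rep(1, 20L), aa)
  w[names(enrichment)] <- w[names(enrichment)] * enrichment
  p_pos <- w / sum(w)
  sample_peps <- function(n, prob) {
    lens <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
    vapply(lens, function(l) {
      paste(sample(aa, l, replace = TRUE, prob = prob), collapse = "")
    }, character(1))
  }
  pos <- sample_peps(n_pos, p_pos)
  neg <- sample_peps(n_neg, NULL)
  tibble::tibble(
    id = c(paste0("pos", seq_len(n_pos)), paste0("neg", seq_len(n_neg))),
    sequence = c(pos, neg),
    label = rep(c(1L, 0L), c(n_pos, n_neg))
  )
}

#' Stratified train/test split
#'
#' Class proportions are preserved in both partitions within one item per
#' class; the partitions are disjoint and exhaustive.
#'
#' @param dataset Tibble with a `label` column.
#' @param ratio Training fraction (default 0.8).
#' @param seed Integer seed (default 702).
#' @return List with tibbles `train` and `test`.
#' @export
stratified_split <- function(dataset, ratio = 0.8, seed = 702L) {
  stopifnot("label" %in% names(dataset))
  tab <- table(dataset$label)
  if (any(tab < 2L)) stop("every class needs at least 2 members to split")
  set.seed(seed)
  train_idx <- integer(0)
  for (cl in names(tab)) {
    idx <- which(dataset$label == cl)
    n_tr <- round(length(idx) * ratio)
    train_idx <- c(train_idx, sample(idx, n_tr))
  }
  train_idx <- sort(train_idx)
  list(train = dataset[train_idx, , drop = FALSE],
       test = dataset[setdiff(seq_len(nrow(dataset)), train_idx), ,
                      drop = FALSE])
}

#' Write a labeled peptide set as FASTA plus label TSV
#'
#' @param peptides Tibble from [simulate_peptides()].
#' @param fasta_path,labels_path Output paths.
#' @return `fasta_path`, invisibly.
#' @export
write_peptide_set <- function(peptides, fasta_path, labels_path) {
  write_fasta(peptides, fasta_path)
  utils::write.table(peptides[, c("id", "label")], labels_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(fasta_path)
}

#' Read a peptide label TSV (id, 0/1) and join onto sequences
#'
#' @param fasta_path Peptide FASTA.
#' @param labels_path Two-column TSV with header `id`, `label`.
#' @return Tibble with `id`, `sequence`, `label`.
#' @export
read_peptide_set <- function(fasta_path, labels_path) {
  seqs <- read_fasta(fasta_path, type = "protein")
  labs <- utils::read.table(labels_path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  out <- dplyr::inner_join(seqs[, c("id", "sequence")], labs, by = "id")
  tibble::tibble(out)
}
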