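# Simulators: determinism, composition targets and cross-module closure.

test_that("genome simulation is byte-reproducible under a seed", {
  s1 <- simulate_genome(length = 10000, n_genes = 5, seed = 3)
  s2 <- simulate_genome(length = 10000, n_genes = 5, seed = 3)
  expect_identical(s1$genome$sequence, s2$genome$sequence)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$codon_table, s2$codon_table)
  s3 <- simulate_genome(length = 10000, n_genes = 5, seed = 4)
  expect_false(identical(s1$genome$sequence, s3$genome$sequence))
})

test_that("background GC tracks the requested level", {
  sim <- simulate_genome(length = 100000, n_genes = 10, gc_background = 0.6,
                         seed = 5)
  # mask gene regions, measure the rest
  chars <- strsplit(sim$genome$sequence, "")[[1]]
  in_gene <- rep(FALSE, length(chars))
  for (i in seq_len(nrow(sim$truth))) {
    in_gene[(sim$truth$start[i] + 1):sim$truth$end[i]] <- TRUE
  }
  bg <- chars[!in_gene]
  expect_lt(abs(mean(bg %in% c("G", "C")) - 0.6), 0.02)
})

test_that("every embedded gene is recovered as a complete stop-matched ORF", {
  sim <- simulate_genome(length = 20000, n_genes = 20, seed = 6)
  cand <- scan_orfs(sim$genome)
  ds <- make_orf_dataset(cand, sim$truth, balance = FALSE)
  expect_equal(sum(ds$label), 20L)
  pos <- ds[ds$label == 1, ]
  expect_true(all(pos$completeness == "complete"))
  # the matched candidate's stop coordinate equals the truth stop
  truth_stop <- ifelse(sim$truth$strand == "+", sim$truth$end,
                       sim$truth$start)
  cand_stop <- ifelse(pos$strand == "+", pos$end, pos$start)
  expect_setequal(cand_stop, truth_stop)
  # balanced mode keeps parity; larger ratios keep more negatives
  b1 <- make_orf_dataset(cand, sim$truth, seed = 1)
  expect_equal(sum(b1$label == 0), 20L)
  b3 <- make_orf_dataset(cand, sim$truth, neg_ratio = 3, seed = 1)
  expect_equal(sum(b3$label == 0), 60L)
  expect_error(make_orf_dataset(cand[FALSE, ], sim$truth), "no candidate")
  # label vectors are reproducible
  expect_identical(b1$label,
                   make_orf_dataset(cand, sim$truth, seed = 1)$label)
})

test_that("peptide simulation plants a cationic/aromatic composition shift", {
  peps <- simulate_peptides(n_pos = 200, n_neg = 200, seed = 702)
  expect_identical(peps,
                   simulate_peptides(n_pos = 200, n_neg = 200, seed = 702))
  ch_pos <- vapply(peps$sequence[peps$label == 1], net_charge, numeric(1),
                   USE.NAMES = FALSE)
  ch_neg <- vapply(peps$sequence[peps$label == 0], net_charge, numeric(1),
                   USE.NAMES = FALSE)
  expect_gt(mean(ch_pos), mean(ch_neg))
  # with no enrichment the classes are compositionally indistinguishable
  null <- simulate_peptides(n_pos = 300, n_neg = 300,
                            enrichment = c(K = 1), seed = 41)
  count_aa <- function(seqs) {
    table(factor(unlist(strsplit(seqs, "")),
                 levels = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]))
  }
  tab <- rbind(count_aa(null$sequence[null$label == 1]),
               count_aa(null$sequence[null$label == 0]))
  expect_gt(suppressWarnings(stats::chisq.test(tab)$p.value), 0.01)
})

test_that("stratified splits preserve proportions and partition the data", {
  ds <- tibble::tibble(id = 1:100, label = rep(c(1, 0), each = 50))
  sp <- stratified_split(ds, ratio = 0.8, seed = 702)
  expect_equal(nrow(sp$train), 80L)
  expect_equal(sum(sp$train$label), 40)
  expect_equal(sum(sp$test$label), 10)
  expect_identical(sp, stratified_split(ds, ratio = 0.8, seed = 702))
  expect_error(stratified_split(tibble::tibble(label = c(1, 0)), 0.5),
               "at least 2")
  set.seed(33)
  for (i in 1:50) {
    n <- sample(20:200, 1)
    ds <- tibble::tibble(id = seq_len(n),
                         label = rbinom(n, 1, runif(1, 0.2, 0.8)))
    if (min(table(ds$label)) < 2) next
    sp <- stratified_split(ds, ratio = 0.7, seed = i)
    expect_setequal(c(sp$train$id, sp$test$id), ds$id)
    expect_length(intersect(sp$train$id, sp$test$id), 0)
    for (cl in 0:1) {
      expect_lte(abs(sum(sp$train$label == cl) -
                       0.7 * sum(ds$label == cl)), 1)
    }
  }
})

test_that("peptide sets round-trip through FASTA plus label TSV", {
  peps <- simulate_peptides(n_pos = 10, n_neg = 10, seed = 1)
  fa <- withr::local_tempfile(fileext = ".fasta")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_peptide_set(peps, fa, tsv)
  back <- read_peptide_set(fa, tsv)
  expect_equal(back$sequence[match(peps$id, back$id)], peps$sequence)
  expect_equal(back$label[match(peps$id, back$id)], peps$label)
})

test_that("stronger codon bias makes the classes more separable", {
  # monotonicity probed at the feature level: distance between mean
  # monocodon profiles of genes and background grows with bias strength
  gaps <- vapply(c(2, 10, 50), function(strength) {
    sim <- simulate_genome(length = 15000, n_genes = 12,
                           codon_bias_strength = strength, seed = 44)
    cand <- scan_orfs(sim$genome)
    ds <- make_orf_dataset(cand, sim$truth, neg_ratio = 1, seed = 44)
    x <- featurize_orfs(ds)
    blocks <- attr(x, "blocks")
    mono <- x[, (blocks$offset[2] + 1):(blocks$offset[2] + 64)]
    sqrt(sum((colMeans(mono[ds$label == 1, , drop = FALSE]) -
                colMeans(mono[ds$label == 0, , drop = FALSE]))^2))
  }, numeric(1))
  expect_true(all(diff(gaps) > 0))
})
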