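# Peptide classifier: tokenizer, channels against step-by-step oracles,
# head behavior, gradients and seeded training.

tiny_pep_config <- function(...) {
  peptide_model_config(cnn_filters = c(5L, 4L, 3L), lstm_hidden = 4L,
                       mlp_widths = c(6L, 4L), max_len = 16L, seed = 5L, ...)
}

test_that("the vocabulary has 26 bijective tokens", {
  v <- peptide_vocab()
  expect_length(v$tokens, 26L)
  expect_equal(sort(unname(v$id_of)), 0:25)
  expect_setequal(v$tokens,
                  c("[PAD]", "[UNK]", "[CLS]", "[SEP]", "[MASK]", "X",
                    strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]))
})

test_that("tokenization adds specials, pads, truncates and maps unknowns", {
  v <- peptide_vocab()
  tok <- tokenize_peptides("ACD", max_len = 6L)
  expect_equal(tok$ids[1, ],
               unname(v$id_of[c("[CLS]", "A", "C", "D", "[SEP]", "[PAD]")]))
  expect_equal(tok$mask[1, ], c(1L, 1L, 1L, 1L, 1L, 0L))
  # unknown residue maps to X before lookup
  tok <- tokenize_peptides("ACB", max_len = 6L)
  expect_equal(tok$ids[1, 4], unname(v$id_of[["X"]]))
  # truncation keeps the first max_len - 2 residues
  tok <- tokenize_peptides("ACDEFGH", max_len = 5L)
  expect_equal(detokenize_peptides(tok$ids), "ACD")
  expect_error(tokenize_peptides(""), "empty")

  set.seed(13)
  seqs <- vapply(sample(3:30, 100, TRUE), random_peptide, character(1))
  tok <- tokenize_peptides(seqs, max_len = 32L)
  expect_equal(detokenize_peptides(tok$ids), seqs)
})

test_that("the CNN channel equals a direct-convolution reference", {
  cfg <- tiny_pep_config()
  m <- build_peptide_model(cfg, embedding_provider(dim = 6L))
  set.seed(14)
  for (rep in 1:10) {
    L <- sample(8:16, 1)
    emb <- matrix(rnorm(L * 6), L, 6)
    got <- cnn_channel(emb, m)
    a1 <- pmax(oracle_conv1d(emb, m$params$cW1, m$params$cb1, 3L), 0)
    a2 <- pmax(oracle_conv1d(a1, m$params$cW2, m$params$cb2, 3L), 0)
    a3 <- pmax(oracle_conv1d(a2, m$params$cW3, m$params$cb3, 3L), 0)
    expect_equal(got, colMeans(a3), tolerance = 1e-5)
  }
  expect_error(cnn_channel(matrix(rnorm(12), 2, 6), m), "pad")
})

test_that("the CNN channel ignores appended pads via its mask", {
  cfg <- tiny_pep_config()
  m <- build_peptide_model(cfg, embedding_provider(dim = 6L))
  set.seed(15)
  emb <- matrix(rnorm(10 * 6), 10, 6)
  base <- cnn_channel(emb, m)
  padded <- rbind(emb, matrix(rnorm(4 * 6), 4, 6))  # arbitrary pad content
  got <- cnn_channel(padded, m, mask = c(rep(1, 10), rep(0, 4)))
  expect_equal(got, base, tolerance = 1e-10)
})

test_that("the BiLSTM channel equals an unrolled recurrence", {
  cfg <- tiny_pep_config()
  m <- build_peptide_model(cfg, embedding_provider(dim = 6L))
  set.seed(16)
  for (rep in 1:10) {
    L <- sample(1:12, 1)
    emb <- matrix(rnorm(L * 6), L, 6)
    got <- bilstm_channel(emb, m)
    fwd <- oracle_lstm_last(emb, rep(1, L), m$params$lfWx, m$params$lfWh,
                            m$params$lfb)
    bwd <- oracle_lstm_last(emb[L:1, , drop = FALSE], rep(1, L),
                            m$params$lbWx, m$params$lbWh, m$params$lbb)
    expect_equal(got, c(fwd, bwd), tolerance = 1e-5)
  }
  # zero weights and biases give a zero representation
  m0 <- m
  for (nm in c("lfWx", "lfWh", "lfb", "lbWx", "lbWh", "lbb")) {
    m0$params[[nm]][] <- 0
  }
  expect_equal(bilstm_channel(matrix(rnorm(30), 5, 6), m0), rep(0, 8))
})

test_that("the head is a sigmoid over batch-normalized channel features", {
  cfg <- tiny_pep_config()
  m <- build_peptide_model(cfg, embedding_provider(dim = 6L))
  emb <- matrix(rnorm(60), 10, 6)
  p <- classify_peptide(cnn_channel(emb, m), bilstm_channel(emb, m), m)
  expect_true(p > 0 && p < 1)
  # zero final-layer weights pin the output at sigmoid(0) = 0.5
  m0 <- m
  m0$params$mW3[] <- 0; m0$params$mb3[] <- 0
  expect_equal(
    classify_peptide(cnn_channel(emb, m0), bilstm_channel(emb, m0), m0), 0.5)
  expect_error(classify_peptide(rnorm(2), rnorm(3), m), "does not match")
})

test_that("peptide backpropagation matches numeric gradients", {
  cfg <- tiny_pep_config()
  m <- build_peptide_model(cfg, embedding_provider(dim = 6L))
  tok <- tokenize_peptides(c("ACDEFGHIK", "KKRWFAML", "MNPQRSTVWYA"),
                           max_len = 16L)
  y <- c(1, 0, 1)
  fw <- orf2pep:::pep_forward(m, tok$ids, tok$mask, training = TRUE)
  l <- orf2pep:::nn_bce(fw$p, y)
  G <- orf2pep:::pep_backward(m, fw$cache, l$dlogit)
  loss_at <- function(params) {
    m2 <- m; m2$params <- params
    orf2pep:::nn_bce(
      orf2pep:::pep_forward(m2, tok$ids, tok$mask, training = TRUE)$p,
      y)$loss
  }
  eps <- 1e-5
  set.seed(17)
  for (nm in names(m$params)) {
    idx <- sample(length(m$params[[nm]]), min(3, length(m$params[[nm]])))
    for (j in idx) {
      up <- m$params; up[[nm]][j] <- up[[nm]][j] + eps
      dn <- m$params; dn[[nm]][j] <- dn[[nm]][j] - eps
      num <- (loss_at(up) - loss_at(dn)) / (2 * eps)
      expect_equal(G[[nm]][j], num, tolerance = 1e-4,
                   label = paste("grad", nm))
    }
  }
})

test_that("an external embedding table loads and is frozen", {
  v <- peptide_vocab()
  f <- withr::local_tempfile(fileext = ".tsv")
  set.seed(18)
  tab <- cbind(v$tokens,
               matrix(round(rnorm(26 * 4), 4), 26, 4))
  utils::write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  prov <- embedding_provider("external_lm", path = f)
  expect_equal(prov$dim, 4L)
  m <- build_peptide_model(tiny_pep_config(), prov)
  expect_null(m$params$Emb)
  expect_equal(dim(m$emb_table), c(26L, 4L))
  # deterministic embeddings at inference
  tok <- tokenize_peptides("ACDEF", max_len = 16L)
  p1 <- orf2pep:::pep_forward(m, tok$ids, tok$mask)$p
  p2 <- orf2pep:::pep_forward(m, tok$ids, tok$mask)$p
  expect_identical(p1, p2)
})

test_that("training is seeded, balanced and learns a planted composition", {
  peps <- simulate_peptides(n_pos = 120, n_neg = 120,
                            len_range = c(10L, 25L), seed = 19)
  cfg <- peptide_model_config(cnn_filters = c(16L, 8L, 8L),
                              lstm_hidden = 8L, mlp_widths = c(16L, 8L),
                              batch_size = 16L, max_epochs = 4L,
                              lr = 1e-3, max_len = 27L, seed = 19L)
  prov <- embedding_provider(dim = 16L)
  m1 <- train_peptide_model(peps, "ACP", cfg, prov)
  m2 <- train_peptide_model(peps, "ACP", cfg, prov)
  expect_identical(m1$history$loss[1], m2$history$loss[1])
  expect_match(m1$training_log[1], "Adam")
  expect_error(train_peptide_model(peps[peps$label == 1, ], "ACP", cfg,
                                   prov), "both classes")
  sc <- predict_peptides(m1, peps)
  expect_true(all(sc$probability >= 0 & sc$probability <= 1))
  expect_gt(mean(sc$probability[peps$label == 1]),
            mean(sc$probability[peps$label == 0]))
  # permutation invariance of batched scoring
  perm <- sample(nrow(peps))
  sc2 <- predict_peptides(m1, peps[perm, ])
  expect_equal(sc2$probability, sc$probability[perm])
})
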