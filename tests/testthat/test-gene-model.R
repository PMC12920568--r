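# Gene model: architecture shapes, exact gradients, determinism, greedy
# resolution and call evaluation.

tiny_gene_config <- function(...) {
  gene_model_config(conv1_filters = 3L, pool1 = 2L, conv2_filters = 4L,
                    pool2 = 2L, fc1_out = 24L, tokens = 4L, token_width = 6L,
                    attn_heads = 2L, fc2_out = 5L, dropout_cnn = 0,
                    dropout_head = 0, seed = 11L, ...)
}

test_that("build produces valid probabilities and derived flatten width", {
  cfg <- tiny_gene_config()
  m <- orf2pep:::build_gene_model(cfg, 40L)
  p1 <- orf2pep:::gene_forward(m, matrix(rnorm(40), 1, 40))$p
  expect_length(p1, 1L)
  expect_true(p1 > 0 && p1 < 1)
  pb <- orf2pep:::gene_forward(m, matrix(rnorm(32 * 40), 32, 40))$p
  expect_length(pb, 32L)
  expect_true(all(pb > 0 & pb < 1))
  expect_error(orf2pep:::build_gene_model(cfg, 5L), "too short")
})

test_that("two builds with the same seed give identical outputs", {
  cfg <- tiny_gene_config()
  set.seed(123)
  x <- matrix(rnorm(3 * 40), 3, 40)
  p1 <- orf2pep:::gene_forward(orf2pep:::build_gene_model(cfg, 40L), x)$p
  p2 <- orf2pep:::gene_forward(orf2pep:::build_gene_model(cfg, 40L), x)$p
  expect_identical(p1, p2)
})

test_that("backpropagation matches numeric gradients", {
  cfg <- tiny_gene_config()
  m <- orf2pep:::build_gene_model(cfg, 40L)
  set.seed(99)
  X <- matrix(rnorm(4 * 40), 4, 40)
  y <- c(1, 0, 1, 0)
  fw <- orf2pep:::gene_forward(m, X, training = TRUE)
  l <- orf2pep:::nn_bce(fw$p, y)
  G <- orf2pep:::gene_backward(m, fw$cache, l$dlogit)
  loss_at <- function(params) {
    m2 <- m; m2$params <- params
    orf2pep:::nn_bce(orf2pep:::gene_forward(m2, X, training = TRUE)$p, y)$loss
  }
  eps <- 1e-5
  for (nm in names(m$params)) {
    idx <- sample(length(m$params[[nm]]), min(4, length(m$params[[nm]])))
    for (j in idx) {
      up <- m$params; up[[nm]][j] <- up[[nm]][j] + eps
      dn <- m$params; dn[[nm]][j] <- dn[[nm]][j] - eps
      num <- (loss_at(up) - loss_at(dn)) / (2 * eps)
      expect_equal(G[[nm]][j], num, tolerance = 1e-4,
                   label = paste("grad", nm))
    }
  }
})

test_that("training is seeded-deterministic and separates planted classes", {
  # two codon-usage populations, linearly inseparable in raw space but
  # separable through the fused statistics
  set.seed(20)
  sim <- simulate_genome(length = 16000, n_genes = 14,
                         codon_bias_strength = 50, seed = 20)
  cand <- scan_orfs(sim$genome)
  ds <- make_orf_dataset(cand, sim$truth, neg_ratio = 2, seed = 20)
  x <- featurize_orfs(ds)
  cfg <- gene_model_config(max_epochs = 8L, seed = 20L)
  m1 <- train_gene_model(x, ds$label, cfg)
  m2 <- train_gene_model(x, ds$label, cfg)
  expect_identical(m1$history$loss, m2$history$loss)
  expect_error(train_gene_model(x, rep(1, nrow(x)), cfg), "both classes")

  p <- predict_orfs(m1, x)$probability
  expect_gt(mean(p[ds$label == 1]), mean(p[ds$label == 0]))
  # duplicated candidate scores identically; batch order is irrelevant
  pdup <- predict_orfs(m1, x[c(1, 1, 2), , drop = FALSE])$probability
  expect_equal(pdup[1], pdup[2])
  perm <- sample(nrow(x))
  pperm <- predict_orfs(m1, x[perm, , drop = FALSE])$probability
  expect_equal(pperm, p[perm])
})

test_that("GC buckets are left-closed deciles with a right-closed end", {
  expect_equal(select_bucket(0.05), 1L)
  expect_equal(select_bucket(0.30), 4L)   # [0.3, 0.4) is the fourth decile
  expect_equal(select_bucket(1.0), 10L)
  expect_equal(select_bucket(0.0), 1L)
  expect_equal(select_bucket(0.999), 10L)
})

test_that("greedy resolution enforces the strictly-more-than rule", {
  base <- tibble::tibble(seq_id = "s", strand = "+",
                         start = c(0L, 39L), end = c(100L, 139L),
                         probability = c(0.9, 0.8))
  kept <- greedy_resolve(base)          # overlap 61 > 60: loser discarded
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$probability, 0.9)
  base$start[2] <- 40L; base$end[2] <- 140L   # overlap exactly 60: both live
  kept <- greedy_resolve(base)
  expect_equal(nrow(kept), 2L)
  # below-threshold candidates never surface
  base$probability[1] <- 0.4
  expect_equal(greedy_resolve(base)$probability, 0.8)
})

test_that("greedy resolution matches the O(n^2) oracle on random sets", {
  set.seed(30)
  for (rep in 1:10) {
    n <- 200
    starts <- sample(0:20000, n, replace = TRUE)
    scored <- tibble::tibble(
      seq_id = sample(c("c1", "c2"), n, replace = TRUE),
      start = starts, end = starts + sample(60:900, n, replace = TRUE),
      strand = sample(c("+", "-"), n, replace = TRUE),
      probability = round(runif(n), 3)
    )
    got <- greedy_resolve(scored)
    want <- oracle_greedy(scored)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$probability, want$probability)
    # invariant: no retained pair on one sequence overlaps > 60 bp
    for (sid in unique(got$seq_id)) {
      g <- got[got$seq_id == sid, ]
      if (nrow(g) > 1) {
        for (i in 1:(nrow(g) - 1)) for (j in (i + 1):nrow(g)) {
          ov <- min(g$end[i], g$end[j]) - max(g$start[i], g$start[j])
          expect_lte(ov, 60)
        }
      }
    }
  }
})

test_that("evaluate_calls scores 3'-end matches", {
  truth <- tibble::tibble(seq_id = "g", start = c(100L, 500L),
                          end = c(400L, 800L), strand = c("+", "-"))
  counts <- evaluate_calls(truth, truth, n_candidates = 10)
  expect_equal(counts$tp, 2L)
  expect_equal(counts$fp, 0L)
  expect_equal(counts$fn, 0L)
  expect_equal(sensitivity(counts), 1)
  expect_equal(specificity(counts), 1)
  # a call with the right stop but different start still counts
  calls <- truth
  calls$start[1] <- 160L
  expect_equal(evaluate_calls(calls, truth)$tp, 2L)
  # empty calls: zero sensitivity
  expect_equal(sensitivity(evaluate_calls(truth[0, ], truth)), 0)
  expect_error(evaluate_calls(truth, truth[0, ]), "empty")
})

test_that("model checkpoints round-trip and guard their version", {
  cfg <- tiny_gene_config()
  m <- orf2pep:::build_gene_model(cfg, 40L)
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(m, f)
  back <- load_model(f)
  expect_identical(back$params, m$params)
  m$format_version <- 99L
  save_model(m, f)
  expect_error(load_model(f), "incompatible checkpoint")
})
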