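# Feature encoding: one-hot, codon statistics, TIS PWM and fusion.

test_that("one_hot maps bases to indicator rows and N/pad to zeros", {
  m <- one_hot(paste0("A", strrep(".", 699)))
  expect_equal(m[1, ], c(A = 1, C = 0, G = 0, T = 0))
  expect_equal(sum(m[-1, ]), 0)

  m <- one_hot(paste0("ACGT", strrep(".", 696)))
  expect_equal(unname(m[1:4, ]), diag(4))

  set.seed(5)
  seq <- random_dna(700)
  m <- one_hot(seq)
  chars <- strsplit(seq, "")[[1]]
  expect_equal(unname(colSums(m)),
               unname(vapply(c("A", "C", "G", "T"),
                             function(b) sum(chars == b), numeric(1))))
  expect_error(one_hot("ACGT"), "700")
})

test_that("monocodon usage is the in-frame codon frequency", {
  v <- monocodon_usage("ATGATGTAA")
  expect_equal(unname(v["ATG"]), 2 / 3)
  expect_equal(unname(v["TAA"]), 1 / 3)
  expect_equal(sum(v), 1)
  expect_equal(unname(monocodon_usage("AAAAAA")["AAA"]), 1)
  # N codons are skipped from numerator and denominator
  v <- monocodon_usage("ATGNNNTAA")
  expect_equal(unname(v["ATG"]), 0.5)
  expect_equal(sum(v), 1)
  expect_equal(sum(monocodon_usage("AT")), 0)

  set.seed(6)
  seq <- random_dna(999)
  v <- monocodon_usage(seq)
  tally <- table(substring(seq, seq(1, 997, 3), seq(3, 999, 3)))
  expect_equal(v[names(tally)], tally / sum(tally),
               ignore_attr = TRUE)
})

test_that("dicodon usage counts overlapping in-frame codon pairs", {
  v <- dicodon_usage("ATGAAATAA")
  expect_equal(unname(v["ATGAAA"]), 0.5)
  expect_equal(unname(v["AAATAA"]), 0.5)
  expect_equal(unname(dicodon_usage("AAAAAAAAA")["AAAAAA"]), 1)
  expect_equal(sum(dicodon_usage("ACGTA")), 0)

  set.seed(7)
  seq <- random_dna(3000)
  v <- dicodon_usage(seq)
  at <- seq(1, 2998, 3)                      # 1,000 in-frame codon starts
  pairs <- substring(seq, at[-length(at)], at[-length(at)] + 5)
  tally <- table(pairs)
  expect_equal(v[names(tally)], tally / sum(tally), ignore_attr = TRUE)
  expect_equal(sum(v), 1)
})

test_that("the TIS PWM recovers planted position preferences", {
  # degenerate alignment: all-A windows against a uniform background
  pwm <- train_tis_pwm(rep(strrep("A", 30), 50))
  expect_true(all(pwm$weights[, "A"] > 0))
  # null case: background equal to the positive composition
  set.seed(8)
  wins <- vapply(rep(30, 800), random_dna, character(1))
  pwm0 <- train_tis_pwm(wins, background_seqs = wins)
  expect_lt(max(abs(pwm0$weights)), 0.35)
  expect_lt(mean(abs(pwm0$weights)), 0.1)
  # parameter recovery from a known PWM
  set.seed(9)
  probs <- matrix(runif(30 * 4, 0.05, 1), 30, 4)
  probs <- probs / rowSums(probs)
  wins <- vapply(1:1000, function(i) {
    paste(vapply(1:30, function(p) {
      sample(c("A", "C", "G", "T"), 1, prob = probs[p, ])
    }, character(1)), collapse = "")
  }, character(1))
  pwm <- train_tis_pwm(wins)
  truth <- log2(probs / 0.25)
  expect_lt(max(abs(pwm$weights - truth)), 0.35)
  expect_lt(mean(abs(pwm$weights - truth)), 0.1)
  expect_error(train_tis_pwm(character(0)), "no positive windows")
})

test_that("tis_score is the per-position table sum", {
  set.seed(10)
  wins <- vapply(rep(30, 100), random_dna, character(1))
  pwm <- train_tis_pwm(wins)
  expect_equal(tis_score("", pwm), 0)
  expect_equal(tis_score("NNN", pwm), 0)
  # consensus maximizes among same-length windows
  consensus <- paste(c("A", "C", "G", "T")[apply(pwm$weights, 1,
                                                 which.max)],
                     collapse = "")
  expect_gte(tis_score(consensus, pwm),
             max(vapply(vapply(rep(30, 50), random_dna, character(1)),
                        tis_score, numeric(1), pwm = pwm)))
  # random window equals an explicit table sum (right-aligned)
  w <- random_dna(17)
  chars <- strsplit(w, "")[[1]]
  pos <- (30 - 17 + 1):30
  manual <- sum(pwm$weights[cbind(pos, match(chars, c("A", "C", "G", "T")))])
  expect_equal(tis_score(w, pwm), manual)
})

test_that("scalar features follow their closed forms", {
  expect_equal(gc_content("ATGC"), 0.5)
  expect_equal(unname(base_composition("AACG")), c(0.5, 0.25, 0.25, 0))
  expect_equal(length_feature(1400, cap = 700), 1)
  expect_equal(length_feature(350, cap = 700), 0.5)
  expect_warning(v <- gc_content("NNN"), "no unambiguous")
  expect_equal(v, 0)
  expect_warning(bc <- base_composition("NN"), "no unambiguous")
  expect_equal(unname(bc), rep(0, 4))
})

test_that("fuse_features concatenates blocks losslessly in fixed order", {
  blocks <- feature_blocks()
  expect_equal(sum(blocks$width), 6967L)
  onehot <- matrix(0, 700, 4)
  zero_bundle <- list(monocodon = numeric(64), dicodon = numeric(4096),
                      tis = 0, orf_length = 0, gc = 0,
                      base_comp = numeric(4))
  expect_equal(fuse_features(onehot, zero_bundle),
               numeric(6967), ignore_attr = TRUE)
  expect_error(fuse_features(onehot, zero_bundle[-2]), "dicodon")

  set.seed(11)
  seq <- random_dna(800)
  onehot <- one_hot(standardize_length(seq))
  bundle <- list(monocodon = monocodon_usage(seq),
                 dicodon = dicodon_usage(seq), tis = 1.5,
                 orf_length = length_feature(800), gc = gc_content(seq),
                 base_comp = base_composition(seq))
  v <- fuse_features(onehot, bundle)
  # slicing at the recorded offsets recovers every block exactly
  slice <- function(name) {
    b <- blocks[blocks$block == name, ]
    v[(b$offset + 1):(b$offset + b$width)]
  }
  expect_equal(slice("one_hot"), as.vector(t(onehot)))
  expect_equal(slice("monocodon"), unname(bundle$monocodon))
  expect_equal(slice("dicodon"), unname(bundle$dicodon))
  expect_equal(slice("tis"), 1.5)
  expect_equal(slice("gc"), gc_content(seq))
  expect_equal(slice("base_comp"), unname(bundle$base_comp))
})

test_that("featurize_orfs yields uniform-width rows with sane blocks", {
  set.seed(12)
  rec <- tibble::tibble(id = "g", sequence = random_dna(6000),
                        length = 6000L)
  cand <- scan_orfs(rec)
  x <- featurize_orfs(cand)
  expect_equal(ncol(x), 6967L)
  expect_equal(nrow(x), nrow(cand))
  expect_equal(rownames(x), cand$orf_id)
  blocks <- attr(x, "blocks")
  mono <- x[, (blocks$offset[2] + 1):(blocks$offset[2] + 64), drop = FALSE]
  di <- x[, (blocks$offset[3] + 1):(blocks$offset[3] + 4096), drop = FALSE]
  expect_true(all(abs(rowSums(mono) - 1) < 1e-12))
  expect_true(all(abs(rowSums(di) - 1) < 1e-12))
  bc <- x[, (blocks$offset[7] + 1):(blocks$offset[7] + 4), drop = FALSE]
  expect_true(all(abs(rowSums(bc) - 1) < 1e-12))
  gc <- x[, blocks$offset[6] + 1]
  expect_true(all(gc >= 0 & gc <= 1))
})
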