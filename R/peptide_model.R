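# Functional-peptide classifier: tokenizer over a 26-token vocabulary,
# pluggable residue-embedding provider, parallel CNN and BiLSTM channels over
# the embeddings, and a batch-normalized three-layer MLP head. One model
# instance is trained per task (ACP or AMP).

#' The 26-token peptide vocabulary
#'
#' Twenty standard amino acids plus `X` (unknown residue) and the five
#' language-model specials `[PAD]`, `[UNK]`, `[CLS]`, `[SEP]`, `[MASK]`.
#'
#' @return A list with `tokens` (ordered, ids 0..25) and `id_of` (named
#'   integer map).
#' @export
peptide_vocab <- function() {
  tokens <- c("[PAD]", "[UNK]", "[CLS]", "[SEP]", "[MASK]",
              c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"), "X")
  list(tokens = tokens,
       id_of = stats::setNames(seq_along(tokens) - 1L, tokens))
}

#' Tokenize peptide sequences
#'
#' Each sequence becomes `[CLS]` + residue ids + `[SEP]`, right-padded with
#' `[PAD]` to `max_len`; residues beyond `max_len - 2` are truncated.
#' Non-standard residues map to `X` before lookup.
#'
#' @param sequences Character vector of peptide sequences (or a tibble with a
#'   `sequence` column).
#' @param vocab A [peptide_vocab()].
#' @param max_len Total tokenized length including specials (default 100).
#' @return A list with integer matrices `ids` and `mask` (n x max_len; ids
#'   are 0-based vocabulary ids, mask is 1 on real tokens) and `lengths`.
#' @export
tokenize_peptides <- function(sequences, vocab = peptide_vocab(),
                              max_len = 100L) {
  if (is.data.frame(sequences)) sequences <- sequences$sequence
  if (any(!nzchar(sequences))) stop("empty peptide sequence")
  n <- length(sequences)
  ids <- matrix(vocab$id_of[["[PAD]"]], n, max_len)
  mask <- matrix(0L, n, max_len)
  aa <- vocab$id_of
  for (i in seq_len(n)) {
    chars <- strsplit(toupper(sequences[i]), "", fixed = TRUE)[[1]]
    chars[!chars %in% names(aa) | chars %in%
            c("[PAD]", "[UNK]", "[CLS]", "[SEP]", "[MASK]")] <- "X"
    chars <- chars[seq_len(min(length(chars), max_len - 2L))]
    row <- c(aa[["[CLS]"]], unname(aa[chars]), aa[["[SEP]"]])
    ids[i, seq_along(row)] <- row
    mask[i, seq_along(row)] <- 1L
  }
  list(ids = ids, mask = mask, lengths = rowSums(mask))
}

#' Recover sequences from token ids
#'
#' Inverse of [tokenize_peptides()] up to `X` substitution and truncation.
#'
#' @param ids Integer matrix of token ids.
#' @param vocab A [peptide_vocab()].
#' @return Character vector of sequences.
#' @export
detokenize_peptides <- function(ids, vocab = peptide_vocab()) {
  specials <- c("[PAD]", "[UNK]", "[CLS]", "[SEP]", "[MASK]")
  apply(ids, 1L, function(r) {
    toks <- vocab$tokens[r + 1L]
    paste(toks[!toks %in% specials], collapse = "")
  })
}

#' Residue-embedding provider
#'
#' Abstracts where per-token embeddings come from. `trainable_lookup`
#' (default) is a randomly initialized token-embedding table trained jointly
#' with the classifier, so no pretrained weights are ever required.
#' `external_lm` loads a frozen per-token embedding table (26 rows, one per
#' vocabulary token, tab-separated: token then D values) exported from any
#' protein language model.
#'
#' @param mode `"trainable_lookup"` or `"external_lm"`.
#' @param dim Embedding dimensionality (ignored for `external_lm`, where it
#'   comes from the table).
#' @param path Path to the embedding table for `external_lm`.
#' @return An object of class `embedding_provider`.
#' @export
embedding_provider <- function(mode = c("trainable_lookup", "external_lm"),
                               dim = 128L, path = NULL) {
  mode <- match.arg(mode)
  table <- NULL
  if (mode == "external_lm") {
    if (is.null(path)) stop("external_lm provider needs a table path")
    raw <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
    vocab <- peptide_vocab()
    m <- as.matrix(raw[, -1L, drop = FALSE])
    if (nrow(m) != 26L) stop("embedding table must have 26 rows")
    rownames(m) <- raw[[1L]]
    m <- m[vocab$tokens, , drop = FALSE]
    if (any(!is.finite(m))) stop("non-finite embedding values")
    table <- unname(m)
    dim <- ncol(m)
  }
  structure(list(mode = mode, dim = as.integer(dim), table = table),
            class = "embedding_provider")
}

#' Peptide-model hyperparameter configuration
#'
#' Defaults follow the published regime: three CNN layers with kernel 3 and
#' 256/128/64 filters, a bidirectional LSTM channel, a batch-normalized
#' three-layer MLP head, batch size 4 and 20 epochs with early stopping. The
#' published learning rate of 2e-5 suits fine-tuning on top of a pretrained
#' language model; training the lookup embeddings from scratch needs a larger
#' step (the package's experiments use 1e-3).
#'
#' @param ... Named overrides of any field.
#' @return A list of class `peptide_model_config`.
#' @export
peptide_model_config <- function(...) {
  cfg <- list(cnn_filters = c(256L, 128L, 64L), cnn_kernel = 3L,
              lstm_hidden = 64L, mlp_widths = c(64L, 32L),
              lr = 2e-5, batch_size = 4L, max_epochs = 20L, patience = 3L,
              seed = 702L, max_len = 100L)
  over <- list(...)
  cfg[names(over)] <- over
  stopifnot(length(cfg$cnn_filters) == 3L, length(cfg$mlp_widths) == 2L,
            all(cfg$cnn_filters > 0L), cfg$lstm_hidden > 0L)
  structure(cfg, class = "peptide_model_config")
}

#' Build an untrained peptide model
#'
#' @param config A [peptide_model_config()].
#' @param provider An [embedding_provider()].
#' @return An object of class `peptide_model`.
#' @export
build_peptide_model <- function(config = peptide_model_config(),
                                provider = embedding_provider()) {
  set.seed(config$seed)
  D <- provider$dim
  k <- config$cnn_kernel
  f <- config$cnn_filters
  H <- config$lstm_hidden
  cw <- f[3] + 2L * H
  m <- config$mlp_widths
  params <- list(
    cW1 = nn_glorot(k * D, f[1], c(k * D, f[1])), cb1 = numeric(f[1]),
    cW2 = nn_glorot(k * f[1], f[2], c(k * f[1], f[2])), cb2 = numeric(f[2]),
    cW3 = nn_glorot(k * f[2], f[3], c(k * f[2], f[3])), cb3 = numeric(f[3]),
    lfWx = nn_glorot(D, 4L * H, c(D, 4L * H)),
    lfWh = nn_glorot(H, 4L * H, c(H, 4L * H)), lfb = numeric(4L * H),
    lbWx = nn_glorot(D, 4L * H, c(D, 4L * H)),
    lbWh = nn_glorot(H, 4L * H, c(H, 4L * H)), lbb = numeric(4L * H),
    bng = rep(1, cw), bnb = numeric(cw),
    mW1 = nn_glorot(cw, m[1], c(cw, m[1])), mb1 = numeric(m[1]),
    mW2 = nn_glorot(m[1], m[2], c(m[1], m[2])), mb2 = numeric(m[2]),
    mW3 = nn_glorot(m[2], 1L, c(m[2], 1L)), mb3 = numeric(1L)
  )
  if (provider$mode == "trainable_lookup") {
    params$Emb <- matrix(stats::rnorm(26L * D, sd = 0.05), 26L, D)
    emb_table <- NULL
  } else {
    emb_table <- provider$table
  }
  structure(
    list(config = config, provider = provider, params = params,
         emb_table = emb_table,
         bn_running = list(mean = numeric(cw), var = rep(1, cw)),
         trained = FALSE, history = NULL, threshold = 0.5,
         training_log = character(), vocab = peptide_vocab(),
         format_version = 1L),
    class = "peptide_model"
  )
}

pep_embed <- function(model, ids) {
  Emb <- model$params$Emb %||% model$emb_table
  n <- nrow(ids); L <- ncol(ids)
  X <- Emb[as.vector(ids) + 1L, , drop = FALSE]
  dim(X) <- c(n, L, ncol(Emb))
  X
}

# Validity mask of pooled conv outputs: position t of the stacked conv
# output is kept only when its whole receptive field (span bp tokens) is
# real, so appended [PAD] tokens never reach the pooled average.
conv_valid_mask <- function(mask, span) {
  n <- nrow(mask); L <- ncol(mask)
  Lc <- L - span + 1L
  out <- mask[, 1:Lc, drop = FALSE]
  for (j in 2:span) out <- out * mask[, j:(j + Lc - 1L), drop = FALSE]
  out
}

# Masked global average pool over (n, Lc, C) given validity PM (n, Lc).
masked_avg_pool <- function(Y, PM) {
  n <- dim(Y)[1]; Lc <- dim(Y)[2]; C <- dim(Y)[3]
  denom <- rowSums(PM)
  if (any(denom == 0)) {
    stop("sequence shorter than the convolutional receptive field; ",
         "pad the input or reduce the kernel size")
  }
  tmp <- Y * as.vector(PM)  # recycles over the channel dim
  tmp <- aperm(tmp, c(2L, 1L, 3L))
  dim(tmp) <- c(Lc, n * C)
  S <- colSums(tmp)
  dim(S) <- c(n, C)
  S / denom
}

masked_avg_pool_backward <- function(dP, PM, dimY) {
  n <- dimY[1]; Lc <- dimY[2]; C <- dimY[3]
  denom <- rowSums(PM)
  dY <- array(0, dim = dimY)
  scaled <- dP / denom  # n x C
  for (c_ in seq_len(C)) dY[, , c_] <- PM * scaled[, c_]
  dY
}

# Forward pass over tokenized batch. Returns probability vector and caches.
pep_forward <- function(model, ids, mask, training = FALSE) {
  cfg <- model$config
  n <- nrow(ids)
  X <- pep_embed(model, ids)
  k <- cfg$cnn_kernel
  P <- model$params
  c1 <- nn_conv1d_forward(X, P$cW1, P$cb1, k); r1 <- nn_relu_forward(c1$out)
  c2 <- nn_conv1d_forward(r1$out, P$cW2, P$cb2, k)
  r2 <- nn_relu_forward(c2$out)
  c3 <- nn_conv1d_forward(r2$out, P$cW3, P$cb3, k)
  r3 <- nn_relu_forward(c3$out)
  PM <- conv_valid_mask(mask, 3L * (k - 1L) + 1L)
  pooled <- masked_avg_pool(r3$out, PM)
  lf <- nn_lstm_forward(X, mask, P$lfWx, P$lfWh, P$lfb)
  rev_idx <- rev(seq_len(ncol(ids)))
  Xr <- X[, rev_idx, , drop = FALSE]
  Mr <- mask[, rev_idx, drop = FALSE]
  lb <- nn_lstm_forward(Xr, Mr, P$lbWx, P$lbWh, P$lbb)
  feat <- cbind(pooled, lf$out, lb$out)
  bn <- nn_batchnorm_forward(feat, P$bng, P$bnb, model$bn_running, training)
  m1 <- nn_dense_forward(bn$out, P$mW1, P$mb1); mr1 <- nn_relu_forward(m1$out)
  m2 <- nn_dense_forward(mr1$out, P$mW2, P$mb2)
  mr2 <- nn_relu_forward(m2$out)
  m3 <- nn_dense_forward(mr2$out, P$mW3, P$mb3)
  p <- nn_sigmoid(as.vector(m3$out))
  list(p = p, running = bn$running,
       cache = if (training) list(ids = ids, mask = mask, X = X,
                                  c1 = c1, r1 = r1, c2 = c2, r2 = r2,
                                  c3 = c3, r3 = r3, PM = PM,
                                  lf = lf, lb = lb, rev_idx = rev_idx,
                                  bn = bn, m1 = m1, mr1 = mr1, m2 = m2,
                                  mr2 = mr2, m3 = m3, n = n,
                                  nc = ncol(pooled), H = cfg$lstm_hidden)
       else NULL)
}

pep_backward <- function(model, cache, dlogit) {
  P <- model$params
  G <- list()
  d3 <- nn_dense_backward(matrix(dlogit, ncol = 1L), P$mW3, cache$m3$cache)
  G$mW3 <- d3$dW; G$mb3 <- d3$db
  dr2 <- nn_relu_backward(d3$dX, cache$mr2$cache)
  d2 <- nn_dense_backward(dr2, P$mW2, cache$m2$cache)
  G$mW2 <- d2$dW; G$mb2 <- d2$db
  dr1 <- nn_relu_backward(d2$dX, cache$mr1$cache)
  d1 <- nn_dense_backward(dr1, P$mW1, cache$m1$cache)
  G$mW1 <- d1$dW; G$mb1 <- d1$db
  bbn <- nn_batchnorm_backward(d1$dX, P$bng, cache$bn$cache)
  G$bng <- bbn$dg; G$bnb <- bbn$db
  nc <- cache$nc; H <- cache$H
  dpooled <- bbn$dX[, 1:nc, drop = FALSE]
  dhf <- bbn$dX[, (nc + 1L):(nc + H), drop = FALSE]
  dhb <- bbn$dX[, (nc + H + 1L):(nc + 2L * H), drop = FALSE]
  dY3 <- masked_avg_pool_backward(dpooled, cache$PM, dim(cache$r3$out))
  dY3 <- nn_relu_backward(dY3, cache$r3$cache)
  b3 <- nn_conv1d_backward(dY3, P$cW3, cache$c3$cache)
  G$cW3 <- b3$dW; G$cb3 <- b3$db
  dY2 <- nn_relu_backward(b3$dX, cache$r2$cache)
  b2 <- nn_conv1d_backward(dY2, P$cW2, cache$c2$cache)
  G$cW2 <- b2$dW; G$cb2 <- b2$db
  dY1 <- nn_relu_backward(b2$dX, cache$r1$cache)
  b1 <- nn_conv1d_backward(dY1, P$cW1, cache$c1$cache)
  G$cW1 <- b1$dW; G$cb1 <- b1$db
  dX <- b1$dX
  blf <- nn_lstm_backward(dhf, P$lfWx, P$lfWh, cache$lf$cache)
  G$lfWx <- blf$dWx; G$lfWh <- blf$dWh; G$lfb <- blf$db
  dX <- dX + blf$dX
  blb <- nn_lstm_backward(dhb, P$lbWx, P$lbWh, cache$lb$cache)
  G$lbWx <- blb$dWx; G$lbWh <- blb$dWh; G$lbb <- blb$db
  dX[, cache$rev_idx, ] <- dX[, cache$rev_idx, , drop = FALSE] + blb$dX
  if (!is.null(P$Emb)) {
    n <- cache$n; L <- ncol(cache$ids); D <- dim(dX)[3]
    dXm <- dX; dim(dXm) <- c(n * L, D)
    G$Emb <- rowsum(dXm, group = as.vector(cache$ids),
                    reorder = FALSE)
    full <- matrix(0, 26L, D)
    full[as.integer(rownames(G$Emb)) + 1L, ] <- G$Emb
    G$Emb <- full
  }
  G[names(model$params)]
}

#' CNN channel over a residue-embedding matrix
#'
#' Three stacked 1-D convolutions (kernel `cnn_kernel`, filter counts
#' `cnn_filters`) with ReLU, followed by masked global average pooling:
#' positions whose receptive field touches padding are excluded, so the
#' output is invariant to appended `[PAD]` tokens.
#'
#' @param embeddings L x D matrix for one peptide.
#' @param model A `peptide_model` supplying the channel weights.
#' @param mask Optional 0/1 validity vector of length L (default all real).
#' @return Fixed-width numeric vector (`cnn_filters[3]` entries).
#' @export
cnn_channel <- function(embeddings, model, mask = NULL) {
  L <- nrow(embeddings)
  k <- model$config$cnn_kernel
  if (L < k) stop("input shorter than the kernel; pad the sequence")
  if (is.null(mask)) mask <- rep(1L, L)
  X <- array(embeddings, dim = c(1L, L, ncol(embeddings)))
  # matches pep_forward layout: (1, L, D) with sample-major rows
  X[1, , ] <- embeddings
  P <- model$params
  a <- nn_relu_forward(nn_conv1d_forward(X, P$cW1, P$cb1, k)$out)$out
  a <- nn_relu_forward(nn_conv1d_forward(a, P$cW2, P$cb2, k)$out)$out
  a <- nn_relu_forward(nn_conv1d_forward(a, P$cW3, P$cb3, k)$out)$out
  PM <- conv_valid_mask(matrix(mask, 1L), 3L * (k - 1L) + 1L)
  as.vector(masked_avg_pool(a, PM))
}

#' BiLSTM channel over a residue-embedding matrix
#'
#' Bidirectional recurrent pass; the output concatenates the forward
#' direction's hidden state at the last real token with the backward
#' direction's hidden state at the first token.
#'
#' @inheritParams cnn_channel
#' @return Numeric vector of length `2 * lstm_hidden`.
#' @export
bilstm_channel <- function(embeddings, model, mask = NULL) {
  L <- nrow(embeddings)
  if (is.null(mask)) mask <- rep(1L, L)
  X <- array(0, dim = c(1L, L, ncol(embeddings)))
  X[1, , ] <- embeddings
  M <- matrix(mask, 1L)
  P <- model$params
  hf <- nn_lstm_forward(X, M, P$lfWx, P$lfWh, P$lfb)$out
  hb <- nn_lstm_forward(X[, L:1, , drop = FALSE], M[, L:1, drop = FALSE],
                        P$lbWx, P$lbWh, P$lbb)$out
  c(as.vector(hf), as.vector(hb))
}

#' Classification head over the two channel outputs
#'
#' Concatenation, batch normalization (running statistics at inference) and
#' a three-layer MLP ending in a sigmoid.
#'
#' @param cnn_vec,lstm_vec Channel outputs (vectors, or matrices with one row
#'   per peptide).
#' @param model A `peptide_model` supplying the head weights.
#' @return Probabilities in (0, 1).
#' @export
classify_peptide <- function(cnn_vec, lstm_vec, model) {
  if (is.null(dim(cnn_vec))) cnn_vec <- matrix(cnn_vec, nrow = 1L)
  if (is.null(dim(lstm_vec))) lstm_vec <- matrix(lstm_vec, nrow = 1L)
  feat <- cbind(cnn_vec, lstm_vec)
  P <- model$params
  if (ncol(feat) != length(P$bng)) {
    stop("channel width ", ncol(feat), " does not match head width ",
         length(P$bng))
  }
  bn <- nn_batchnorm_forward(feat, P$bng, P$bnb, model$bn_running,
                             training = FALSE)
  a <- nn_relu_forward(nn_dense_forward(bn$out, P$mW1, P$mb1)$out)$out
  a <- nn_relu_forward(nn_dense_forward(a, P$mW2, P$mb2)$out)$out
  as.vector(nn_sigmoid(nn_dense_forward(a, P$mW3, P$mb3)$out))
}

#' Train a peptide classifier for one task
#'
#' Binary cross-entropy objective optimized with Adam (the adaptive fallback
#' for the published Adafactor regime, recorded in the model's training log)
#' at `config$lr`. An internal stratified 8:2 train/validation split under
#' `config$seed` drives early stopping on validation loss with
#' `config$patience`; the minority class is oversampled to parity in every
#' epoch. Per-epoch validation accuracy, F1 and MCC are recorded.
#'
#' @param peptides Tibble with `id`, `sequence`, `label` (0/1).
#' @param task `"ACP"` or `"AMP"` (metadata carried on the model).
#' @param config A [peptide_model_config()].
#' @param provider An [embedding_provider()].
#' @return A trained `peptide_model` with a `history` tibble.
#' @export
train_peptide_model <- function(peptides, task = c("ACP", "AMP"),
                                config = peptide_model_config(),
                                provider = embedding_provider()) {
  task <- match.arg(task)
  y <- as.numeric(peptides$label)
  if (length(unique(y)) < 2L) stop("training data must contain both classes")
  model <- build_peptide_model(config, provider)
  model$task <- task
  model$training_log <- c(model$training_log,
                          "optimizer: Adam (adaptive fallback), lr = " %+%
                            format(config$lr))
  tok <- tokenize_peptides(peptides$sequence, model$vocab, config$max_len)
  split <- stratified_split(tibble::tibble(idx = seq_along(y), label = y),
                            ratio = 0.8, seed = config$seed)
  tr <- split$train$idx; va <- split$test$idx
  set.seed(config$seed + 1L)
  state <- nn_adam_init(model$params)
  best_val <- Inf; best_params <- model$params; best_running <- model$bn_running
  wait <- 0L
  hist <- list()
  for (epoch in seq_len(config$max_epochs)) {
    ord <- tr[balanced_epoch_order(y[tr])]
    losses <- c()
    for (s in seq(1L, length(ord), by = config$batch_size)) {
      idx <- ord[s:min(s + config$batch_size - 1L, length(ord))]
      if (length(idx) < 2L) next
      fw <- pep_forward(model, tok$ids[idx, , drop = FALSE],
                        tok$mask[idx, , drop = FALSE], training = TRUE)
      model$bn_running <- fw$running
      l <- nn_bce(fw$p, y[idx])
      grads <- pep_backward(model, fw$cache, l$dlogit)
      upd <- nn_adam_step(model$params, grads, state, config$lr)
      model$params <- upd$params; state <- upd$state
      losses <- c(losses, l$loss)
    }
    vp <- pep_forward(model, tok$ids[va, , drop = FALSE],
                      tok$mask[va, , drop = FALSE], training = FALSE)$p
    vl <- nn_bce(vp, y[va])$loss
    cm <- confusion_counts(vp >= 0.5, y[va] == 1)
    # a degenerate epoch may predict a single class; report 0 rather than
    # aborting the run
    f1 <- if (cm$tp == 0) 0 else f1_score(cm)
    hist[[epoch]] <- tibble::tibble(
      epoch = epoch, loss = mean(losses), val_loss = vl,
      val_accuracy = accuracy(cm), val_f1 = f1,
      val_mcc = suppressWarnings(mcc(cm))
    )
    if (vl < best_val - 1e-6) {
      best_val <- vl; best_params <- model$params
      best_running <- model$bn_running; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  model$params <- best_params
  model$bn_running <- best_running
  model$history <- dplyr::bind_rows(hist)
  model$trained <- TRUE
  model
}

`%+%` <- function(a, b) paste0(a, b)

#' Score peptides with a trained model
#'
#' @param model Trained `peptide_model`.
#' @param peptides Tibble with `id`, `sequence` (or a character vector).
#' @param threshold Probability cutoff for the positive label (default 0.5).
#' @param batch_size Inference batch size.
#' @return Tibble with `id`, `task`, `probability`, `label`.
#' @export
predict_peptides <- function(model, peptides, threshold = 0.5,
                             batch_size = 64L) {
  if (!isTRUE(model$trained)) stop("model has not been trained")
  if (is.character(peptides)) {
    peptides <- tibble::tibble(id = paste0("pep", seq_along(peptides)),
                               sequence = peptides)
  }
  tok <- tokenize_peptides(peptides$sequence, model$vocab,
                           model$config$max_len)
  n <- nrow(tok$ids)
  p <- numeric(n)
  for (s in seq(1L, n, by = batch_size)) {
    idx <- s:min(s + batch_size - 1L, n)
    p[idx] <- pep_forward(model, tok$ids[idx, , drop = FALSE],
                          tok$mask[idx, , drop = FALSE],
                          training = FALSE)$p
  }
  tibble::tibble(
    id = peptides$id,
    task = model$task %||% "ACP",
    probability = p,
    label = ifelse(p >= threshold, "positive", "negative")
  )
}
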