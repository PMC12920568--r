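# Minimal neural-network engine used by both classifiers: 1-D convolution,
# pooling, dense layers, layer/batch normalization, multi-head self-attention
# and (bi)LSTM recurrence, each with hand-written backward passes, plus Adam.
#
# Conventions: batched sequence tensors are 3-D arrays with dims
# (batch n, positions L, channels C); R's column-major layout means an
# (n, L, C) array reshaped to an (n*L) x C matrix keeps row r = i + (t-1)*n,
# which all reshapes below rely on. Caches needed for the backward pass are
# returned alongside the forward output.

nn_glorot <- function(fan_in, fan_out, dims = c(fan_in, fan_out)) {
  limit <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -limit, limit), dim = dims)
}

nn_sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- 1-D convolution (valid padding, stride 1) ------------------------------

# X: (n, L, Cin); W: (k*Cin, Cout) with rows ordered offset-major then
# channel; b: length Cout.
nn_conv1d_forward <- function(X, W, b, k) {
  d <- dim(X); n <- d[1]; L <- d[2]; Cin <- d[3]
  Lout <- L - k + 1L
  if (Lout < 1L) stop("input length ", L, " shorter than kernel ", k)
  cols <- vector("list", k)
  for (j in seq_len(k)) {
    block <- X[, j:(j + Lout - 1L), , drop = FALSE]
    dim(block) <- c(n * Lout, Cin)
    cols[[j]] <- block
  }
  Xcol <- do.call(cbind, cols)
  Y <- Xcol %*% W
  Y <- Y + rep(b, each = nrow(Y))
  dim(Y) <- c(n, Lout, ncol(W))
  list(out = Y, cache = list(Xcol = Xcol, dimX = d, k = k))
}

nn_conv1d_backward <- function(dY, W, cache) {
  d <- cache$dimX; n <- d[1]; L <- d[2]; Cin <- d[3]; k <- cache$k
  Lout <- L - k + 1L
  Cout <- ncol(W)
  dYm <- dY; dim(dYm) <- c(n * Lout, Cout)
  dW <- crossprod(cache$Xcol, dYm)
  db <- colSums(dYm)
  dXcol <- dYm %*% t(W)
  dX <- array(0, dim = d)
  for (j in seq_len(k)) {
    block <- dXcol[, ((j - 1L) * Cin + 1L):(j * Cin), drop = FALSE]
    dim(block) <- c(n, Lout, Cin)
    dX[, j:(j + Lout - 1L), ] <- dX[, j:(j + Lout - 1L), , drop = FALSE] + block
  }
  list(dX = dX, dW = dW, db = db)
}

# ---- max pooling -------------------------------------------------------------

nn_maxpool_forward <- function(X, p) {
  d <- dim(X); n <- d[1]; L <- d[2]; C <- d[3]
  Lp <- L %/% p
  if (Lp < 1L) stop("input length ", L, " shorter than pool size ", p)
  best <- X[, seq(1L, by = p, length.out = Lp), , drop = FALSE]
  which_w <- array(1, dim = c(n, Lp, C))
  if (p > 1L) {
    for (w in 2:p) {
      cand <- X[, seq(w, by = p, length.out = Lp), , drop = FALSE]
      upd <- cand > best  # ties keep the first (5'-most) winner
      best <- best + (cand - best) * upd
      which_w <- which_w + (w - which_w) * upd
    }
  }
  list(out = best, cache = list(which_w = which_w, dimX = d, p = p, Lp = Lp))
}

nn_maxpool_backward <- function(dY, cache) {
  d <- cache$dimX; p <- cache$p; Lp <- cache$Lp
  dX <- array(0, dim = d)
  n <- d[1]; C <- d[3]
  # linear index of position t = (b-1)*p + w for pooled block b, winner w
  i <- rep(seq_len(n), times = Lp * C)
  b <- rep(rep(seq_len(Lp), each = n), times = C)
  c_ <- rep(seq_len(C), each = n * Lp)
  t_ <- (b - 1L) * p + as.vector(cache$which_w)
  dX[i + (t_ - 1) * n + (c_ - 1) * n * d[2]] <- as.vector(dY)
  dX
}

# ---- dense -------------------------------------------------------------------

nn_dense_forward <- function(X, W, b) {
  Y <- X %*% W
  list(out = Y + rep(b, each = nrow(Y)), cache = X)
}

nn_dense_backward <- function(dY, W, cache) {
  list(dX = dY %*% t(W), dW = crossprod(cache, dY), db = colSums(dY))
}

# ---- relu / dropout ----------------------------------------------------------

nn_relu_forward <- function(X) {
  mask <- X > 0
  list(out = X * mask, cache = mask)
}

nn_relu_backward <- function(dY, mask) {
  dY * mask
}

nn_dropout_forward <- function(X, rate, training) {
  if (!training || rate <= 0) return(list(out = X, cache = NULL))
  mask <- array(stats::rbinom(length(X), 1L, 1 - rate), dim = dim(X)) /
    (1 - rate)
  list(out = X * mask, cache = mask)
}

nn_dropout_backward <- function(dY, mask) {
  if (is.null(mask)) dY else dY * mask
}

# ---- layer normalization (over the last dim of an (rows x D) matrix) --------

nn_layernorm_forward <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  out <- sweep(sweep(xhat, 2L, g, "*"), 2L, b, "+")
  list(out = out, cache = list(xhat = xhat, inv = inv))
}

nn_layernorm_backward <- function(dY, g, cache) {
  xhat <- cache$xhat; inv <- cache$inv
  D <- ncol(dY)
  dg <- colSums(dY * xhat)
  db <- colSums(dY)
  dxhat <- sweep(dY, 2L, g, "*")
  dX <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dX = dX, dg = dg, db = db)
}

# ---- batch normalization (feature vectors, batch dim = rows) ----------------

nn_batchnorm_forward <- function(X, g, b, running, training,
                                 momentum = 0.1, eps = 1e-5) {
  if (training) {
    mu <- colMeans(X)
    v <- colMeans(sweep(X, 2L, mu)^2)
    running$mean <- (1 - momentum) * running$mean + momentum * mu
    running$var <- (1 - momentum) * running$var + momentum * v
  } else {
    mu <- running$mean
    v <- running$var
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(X, 2L, mu), 2L, inv, "*")
  out <- sweep(sweep(xhat, 2L, g, "*"), 2L, b, "+")
  list(out = out, cache = list(xhat = xhat, inv = inv, n = nrow(X)),
       running = running)
}

nn_batchnorm_backward <- function(dY, g, cache) {
  xhat <- cache$xhat; inv <- cache$inv; n <- cache$n
  dg <- colSums(dY * xhat)
  db <- colSums(dY)
  dxhat <- sweep(dY, 2L, g, "*")
  dX <- sweep(dxhat - matrix(colMeans(dxhat), n, ncol(dY), byrow = TRUE) -
                xhat * matrix(colMeans(dxhat * xhat), n, ncol(dY),
                              byrow = TRUE),
              2L, inv, "*")
  list(dX = dX, dg = dg, db = db)
}

# ---- multi-head self-attention ----------------------------------------------

# Xm: (n*T) x D matrix (row r = sample i at token t with r = i + (t-1)*n).
# Returns attention output (n*T) x D before the output projection.
nn_mha_forward <- function(Xm, Wq, Wk, Wv, Wo, n, T_, heads) {
  D <- ncol(Xm)
  dh <- D %/% heads
  Q <- Xm %*% Wq; K <- Xm %*% Wk; V <- Xm %*% Wv
  O <- matrix(0, nrow(Xm), D)
  A <- vector("list", n)
  scale <- 1 / sqrt(dh)
  for (i in seq_len(n)) {
    rows <- i + (seq_len(T_) - 1L) * n
    Ai <- vector("list", heads)
    for (h in seq_len(heads)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      Qi <- Q[rows, cols, drop = FALSE]
      Ki <- K[rows, cols, drop = FALSE]
      Vi <- V[rows, cols, drop = FALSE]
      S <- tcrossprod(Qi, Ki) * scale
      S <- S - apply(S, 1L, max)  # stable softmax
      E <- exp(S)
      P <- E / rowSums(E)
      O[rows, cols] <- P %*% Vi
      Ai[[h]] <- P
    }
    A[[i]] <- Ai
  }
  out <- O %*% Wo
  list(out = out,
       cache = list(Xm = Xm, Q = Q, K = K, V = V, O = O, A = A,
                    n = n, T_ = T_, heads = heads, dh = dh, scale = scale))
}

nn_mha_backward <- function(dOut, Wq, Wk, Wv, Wo, cache) {
  n <- cache$n; T_ <- cache$T_; heads <- cache$heads; dh <- cache$dh
  scale <- cache$scale
  dWo <- crossprod(cache$O, dOut)
  dO <- dOut %*% t(Wo)
  dQ <- matrix(0, nrow(dO), ncol(dO))
  dK <- dQ; dV <- dQ
  for (i in seq_len(n)) {
    rows <- i + (seq_len(T_) - 1L) * n
    for (h in seq_len(heads)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      P <- cache$A[[i]][[h]]
      Qi <- cache$Q[rows, cols, drop = FALSE]
      Ki <- cache$K[rows, cols, drop = FALSE]
      Vi <- cache$V[rows, cols, drop = FALSE]
      dOi <- dO[rows, cols, drop = FALSE]
      dP <- tcrossprod(dOi, Vi)
      dV[rows, cols] <- crossprod(P, dOi)
      dS <- P * (dP - rowSums(dP * P))  # softmax backward
      dS <- dS * scale
      dQ[rows, cols] <- dS %*% Ki
      dK[rows, cols] <- crossprod(dS, Qi)
    }
  }
  Xm <- cache$Xm
  list(dX = dQ %*% t(Wq) + dK %*% t(Wk) + dV %*% t(Wv),
       dWq = crossprod(Xm, dQ), dWk = crossprod(Xm, dK),
       dWv = crossprod(Xm, dV), dWo = dWo)
}

# ---- LSTM (one direction, masked carry for right-padded batches) ------------

# X: (n, L, D); M: (n, L) 0/1 mask. Params: Wx (D x 4H), Wh (H x 4H), b (4H)
# with gate order input, forget, cell, output. Returns the final hidden state
# (n x H): padded steps carry the previous state forward, so this is the
# state at each sequence's last real token.
nn_lstm_forward <- function(X, M, Wx, Wh, b) {
  d <- dim(X); n <- d[1]; L <- d[2]; D <- d[3]
  H <- ncol(Wh) %/% 4L
  h <- matrix(0, n, H); cc <- matrix(0, n, H)
  steps <- vector("list", L)
  for (t in seq_len(L)) {
    xt <- X[, t, , drop = TRUE]
    if (n == 1L) xt <- matrix(xt, 1L, D)
    z <- xt %*% Wx + h %*% Wh
    z <- z + rep(b, each = n)
    ig <- nn_sigmoid(z[, 1:H, drop = FALSE])
    fg <- nn_sigmoid(z[, (H + 1):(2 * H), drop = FALSE])
    gg <- tanh(z[, (2 * H + 1):(3 * H), drop = FALSE])
    og <- nn_sigmoid(z[, (3 * H + 1):(4 * H), drop = FALSE])
    c_new <- fg * cc + ig * gg
    tc <- tanh(c_new)
    h_new <- og * tc
    m <- M[, t]
    h_next <- m * h_new + (1 - m) * h
    c_next <- m * c_new + (1 - m) * cc
    steps[[t]] <- list(xt = xt, h_prev = h, c_prev = cc, ig = ig, fg = fg,
                       gg = gg, og = og, c_new = c_new, tc = tc, m = m)
    h <- h_next; cc <- c_next
  }
  list(out = h, cache = list(steps = steps, dims = d, H = H))
}

nn_lstm_backward <- function(dh_final, Wx, Wh, cache) {
  d <- cache$dims; n <- d[1]; L <- d[2]; D <- d[3]; H <- cache$H
  dWx <- matrix(0, D, 4L * H); dWh <- matrix(0, H, 4L * H)
  db <- numeric(4L * H)
  dX <- array(0, dim = d)
  dh <- dh_final
  dc <- matrix(0, n, H)
  for (t in rev(seq_len(L))) {
    s <- cache$steps[[t]]
    m <- s$m
    dh_new <- m * dh
    dc_new <- m * dc
    dh_carry <- (1 - m) * dh
    dc_carry <- (1 - m) * dc
    dog <- dh_new * s$tc
    dc_new <- dc_new + dh_new * s$og * (1 - s$tc^2)
    dig <- dc_new * s$gg
    dfg <- dc_new * s$c_prev
    dgg <- dc_new * s$ig
    dc_prev <- dc_new * s$fg
    dz <- cbind(dig * s$ig * (1 - s$ig),
                dfg * s$fg * (1 - s$fg),
                dgg * (1 - s$gg^2),
                dog * s$og * (1 - s$og))
    dWx <- dWx + crossprod(s$xt, dz)
    dWh <- dWh + crossprod(s$h_prev, dz)
    db <- db + colSums(dz)
    dX[, t, ] <- dz %*% t(Wx)
    dh <- dz %*% t(Wh) + dh_carry
    dc <- dc_prev + dc_carry
  }
  list(dX = dX, dWx = dWx, dWh = dWh, db = db)
}

# ---- losses ------------------------------------------------------------------

# Binary cross-entropy on sigmoid probabilities; returns loss and the
# gradient with respect to the pre-sigmoid logit (p - y, the usual shortcut).
nn_bce <- function(p, y, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  list(loss = -mean(y * log(p) + (1 - y) * log(1 - p)),
       dlogit = (p - y) / length(y))
}

# ---- Adam --------------------------------------------------------------------

nn_adam_init <- function(params) {
  list(m = purrr::map(params, function(p) array(0, dim = dim(p) %||% length(p))),
       v = purrr::map(params, function(p) array(0, dim = dim(p) %||% length(p))),
       t = 0L)
}

nn_adam_step <- function(params, grads, state, lr,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
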