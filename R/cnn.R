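# Minimal convolutional-network engine.
#
# No deep-learning backend is available in this stack, so the network is
# implemented directly: valid 3x3 convolutions via im2col + BLAS matrix
# multiplication, 2x2 max pooling, a dense sigmoid head, binary
# cross-entropy and Adam. Activations for a batch of B images are stored as
# matrices [H*W*C, B] with column-major image linearization, so gathers and
# scatters are single indexing operations.

# Linear indices of every k x k patch of an H x W x C image.
# Rows: patch positions (row-major within the output image, row fastest);
# columns: patch elements ordered (dh, dw, channel), dh fastest — the same
# order as the convolution weight matrix rows.
im2col_idx <- function(H, W, C, k = 3L) {
  Ho <- H - k + 1L
  Wo <- W - k + 1L
  i <- rep(seq_len(Ho), times = Wo)            # patch top row
  j <- rep(seq_len(Wo), each = Ho)             # patch left col
  dh <- rep(seq_len(k) - 1L, times = k * C)
  dw <- rep(rep(seq_len(k) - 1L, each = k), times = C)
  ch <- rep(seq_len(C) - 1L, each = k * k)
  # [P, Q] via outer combination
  outer(i, dh, `+`) + H * (outer(j - 1L, dw, `+`)) + H * W *
    matrix(ch, nrow = Ho * Wo, ncol = k * k * C, byrow = TRUE)
}

# Linear indices of the 4 inputs of every 2x2 pooling window over an
# Ho x Wo x C activation. Returns [n_out, 4].
pool_idx <- function(Ho, Wo, C) {
  Hp <- Ho %/% 2L
  Wp <- Wo %/% 2L
  i <- rep(rep(seq_len(Hp), times = Wp), times = C)
  j <- rep(rep(seq_len(Wp), each = Hp), times = C)
  f <- rep(seq_len(C), each = Hp * Wp)
  base <- (2L * i - 1L) + (2L * j - 2L) * Ho + (f - 1L) * Ho * Wo
  cbind(base, base + 1L, base + Ho, base + Ho + 1L)
}

conv_forward <- function(X, idx, Wm, b) {
  P <- nrow(idx)
  Q <- ncol(idx)
  B <- ncol(X)
  A <- X[as.vector(idx), , drop = FALSE]       # [P*Q, B], p fastest
  dim(A) <- c(P, Q, B)
  A <- aperm(A, c(1, 3, 2))                    # [P, B, Q]
  dim(A) <- c(P * B, Q)
  Z <- A %*% Wm                                # [P*B, F]
  Z <- Z + rep(b, each = P * B)
  list(Z = Z, A = A, P = P, B = B)
}

# reshape conv output [P*B, F] (p fastest, then batch) to activation layout
# [P*F, B]
conv_to_act <- function(Z, P, B) {
  F_ <- ncol(Z)
  dim(Z) <- c(P, B, F_)
  O <- aperm(Z, c(1, 3, 2))
  dim(O) <- c(P * F_, B)
  O
}

# inverse of conv_to_act for gradients
act_to_conv <- function(dO, P, B) {
  F_ <- length(dO) / (P * B)
  dim(dO) <- c(P, F_, B)
  dZ <- aperm(dO, c(1, 3, 2))
  dim(dZ) <- c(P * B, F_)
  dZ
}

conv_backward <- function(dZ, A, Wm, idx, n_in, B) {
  dW <- crossprod(A, dZ)
  db <- colSums(dZ)
  dA <- dZ %*% t(Wm)                           # [P*B, Q]
  P <- nrow(idx)
  dim(dA) <- c(P, B, ncol(idx))
  dX <- matrix(0, n_in, B)
  for (q in seq_len(ncol(idx)))
    dX[idx[, q], ] <- dX[idx[, q], ] + dA[, , q]
  list(dW = dW, db = db, dX = dX)
}

pool_forward <- function(X, pidx) {
  B <- ncol(X)
  n_out <- nrow(pidx)
  best <- X[pidx[, 1], , drop = FALSE]
  sel <- matrix(1L, n_out, B)
  for (m in 2:4) {
    cand <- X[pidx[, m], , drop = FALSE]
    upd <- cand > best
    best[upd] <- cand[upd]
    sel[upd] <- m
  }
  list(out = best, sel = sel)
}

pool_backward <- function(dOut, sel, pidx, n_in, B) {
  dX <- matrix(0, n_in, B)
  for (m in 1:4)
    dX[pidx[, m], ] <- dOut * (sel == m)
  dX
}

# Architecture bookkeeping: layer shapes for a square grayscale input.
cnn_dims <- function(input_shape, filters = c(16L, 32L), kernel = 3L) {
  H <- input_shape[1]
  W <- input_shape[2]
  H1 <- H - kernel + 1L; W1 <- W - kernel + 1L
  Hp1 <- H1 %/% 2L; Wp1 <- W1 %/% 2L
  H2 <- Hp1 - kernel + 1L; W2 <- Wp1 - kernel + 1L
  Hp2 <- H2 %/% 2L; Wp2 <- W2 %/% 2L
  if (H2 < 1L || W2 < 1L || Hp2 < 1L || Wp2 < 1L)
    stop_peakfluo("input %dx%d too small for the conv/pool stack", H, W)
  list(H = H, W = W, kernel = kernel, filters = filters,
       H1 = H1, W1 = W1, Hp1 = Hp1, Wp1 = Wp1,
       H2 = H2, W2 = W2, Hp2 = Hp2, Wp2 = Wp2,
       flat = Hp2 * Wp2 * filters[2])
}

cnn_init_params <- function(dims, seed) {
  k <- dims$kernel
  with_seed(seed, {
    he <- function(fan_in, n) matrix(stats::rnorm(n * fan_in, 0,
                                                  sqrt(2 / fan_in)),
                                     fan_in, n)
    list(W1 = he(k * k, dims$filters[1]), b1 = numeric(dims$filters[1]),
         W2 = he(k * k * dims$filters[1], dims$filters[2]),
         b2 = numeric(dims$filters[2]),
         W3 = he(dims$flat, 1L), b3 = 0)
  })
}

cnn_forward_full <- function(model, X, keep_cache = FALSE) {
  d <- model$dims
  p <- model$params
  B <- ncol(X)
  c1 <- conv_forward(X, model$idx1, p$W1, p$b1)
  O1 <- conv_to_act(c1$Z, c1$P, B)
  R1 <- pmax(O1, 0)
  pl1 <- pool_forward(R1, model$pidx1)
  c2 <- conv_forward(pl1$out, model$idx2, p$W2, p$b2)
  O2 <- conv_to_act(c2$Z, c2$P, B)
  R2 <- pmax(O2, 0)
  pl2 <- pool_forward(R2, model$pidx2)
  flat <- pl2$out                               # [flat, B]
  logits <- as.numeric(crossprod(p$W3, flat) + p$b3)
  prob <- stats::plogis(logits)
  out <- list(prob = prob, logits = logits)
  if (keep_cache)
    out$cache <- list(X = X, c1 = c1, O1 = O1, pl1 = pl1,
                      c2 = c2, O2 = O2, pl2 = pl2, flat = flat, B = B)
  out
}

cnn_loss_grads <- function(model, X, y) {
  d <- model$dims
  p <- model$params
  fw <- cnn_forward_full(model, X, keep_cache = TRUE)
  ch <- fw$cache
  B <- ch$B
  eps <- 1e-12
  loss <- -mean(y * log(fw$prob + eps) + (1 - y) * log(1 - fw$prob + eps))
  dlogit <- (fw$prob - y) / B                   # [B]
  dW3 <- ch$flat %*% dlogit
  db3 <- sum(dlogit)
  dflat <- p$W3 %*% matrix(dlogit, 1L)          # [flat, B]
  n_R2 <- d$H2 * d$W2 * d$filters[2]
  dR2 <- pool_backward(dflat, ch$pl2$sel, model$pidx2, n_R2, B)
  dO2 <- dR2 * (ch$O2 > 0)
  dZ2 <- act_to_conv(dO2, ch$c2$P, B)
  n_pl1 <- d$Hp1 * d$Wp1 * d$filters[1]
  bk2 <- conv_backward(dZ2, ch$c2$A, p$W2, model$idx2, n_pl1, B)
  n_R1 <- d$H1 * d$W1 * d$filters[1]
  dR1 <- pool_backward(bk2$dX, ch$pl1$sel, model$pidx1, n_R1, B)
  dO1 <- dR1 * (ch$O1 > 0)
  dZ1 <- act_to_conv(dO1, ch$c1$P, B)
  dW1 <- crossprod(ch$c1$A, dZ1)
  db1 <- colSums(dZ1)
  list(loss = loss,
       grads = list(W1 = dW1, b1 = db1, W2 = bk2$dW, b2 = bk2$db,
                    W3 = dW3, b3 = db3))
}

adam_state <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

adam_step <- function(params, grads, state, t, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    st <- state[[nm]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g^2
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    state[[nm]] <- st
  }
  list(params = params, state = state)
}

cnn_train_params <- function(model, X, y, epochs = 12L, batch_size = 32L,
                             lr = 1e-3, seed = 1L, loss_tol = 0.02) {
  n <- ncol(X)
  state <- adam_state(model$params)
  t <- 0L
  history <- numeric(0)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / batch_size))
      ep_loss <- 0
      for (bt in batches) {
        lg <- cnn_loss_grads(model, X[, bt, drop = FALSE], y[bt])
        t <- t + 1L
        upd <- adam_step(model$params, lg$grads, state, t, lr = lr)
        model$params <- upd$params
        state <- upd$state
        ep_loss <- ep_loss + lg$loss * length(bt)
      }
      history <- c(history, ep_loss / n)
      if (history[length(history)] < loss_tol) break
    }
  })
  model$history <- history
  model
}
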