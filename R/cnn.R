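# A compact convolutional network implemented directly on BLAS matrix
# products (im2col), sized for CPU training on single-channel organoid
# crops. Three conv/relu/maxpool blocks and a small dense head; Adam
# optimiser; all randomness drawn from R's RNG so a fixed seed reproduces
# weights exactly on a fixed platform.
#
# Feature maps are stored as (H*W) x C matrices, column-major per channel.

conv_index <- function(H, W, kh, kw) {
  out_h <- H - kh + 1; out_w <- W - kw + 1
  base_r <- rep(seq_len(out_h), times = out_w)
  base_c <- rep(seq_len(out_w), each = out_h)
  off_r <- rep(seq_len(kh), times = kw)
  off_c <- rep(seq_len(kw), each = kh)
  # (out_h*out_w) x (kh*kw) linear indices into an H x W matrix
  idx <- outer(base_r, off_r - 1L, "+") + (outer(base_c, off_c - 1L, "+") - 1L) * H
  list(idx = idx, out_h = out_h, out_w = out_w, kh = kh, kw = kw)
}

im2col <- function(X, ci) {
  C <- ncol(X)
  out <- matrix(0, nrow(ci$idx), ncol(ci$idx) * C)
  k <- ncol(ci$idx)
  for (c in seq_len(C))
    out[, ((c - 1) * k + 1):(c * k)] <- matrix(X[ci$idx + (c - 1) * nrow(X)],
                                               nrow(ci$idx), k)
  out
}

col2im <- function(dpatch, ci, H, W, C) {
  dX <- matrix(0, H * W, C)
  k <- ncol(ci$idx)
  for (c in seq_len(C)) {
    dc <- dpatch[, ((c - 1) * k + 1):(c * k), drop = FALSE]
    acc <- matrix(0, H, W)
    for (j in seq_len(k)) {
      tgt <- ci$idx[, j]
      # indices within one kernel offset are unique: direct add
      acc[tgt] <- acc[tgt] + dc[, j]
    }
    dX[, c] <- as.vector(acc)
  }
  dX
}

maxpool2 <- function(X, H, W) {
  C <- ncol(X)
  oh <- H %/% 2; ow <- W %/% 2
  out <- matrix(0, oh * ow, C)
  arg <- matrix(0L, oh * ow, C)
  ro <- rep(seq(1, 2 * oh, by = 2), times = ow)
  co <- rep(seq(1, 2 * ow, by = 2), each = oh)
  cand <- cbind(ro + (co - 1) * H, ro + 1 + (co - 1) * H,
                ro + co * H, ro + 1 + co * H)
  for (c in seq_len(C)) {
    v <- matrix(X[cand, c], nrow(cand), 4)
    am <- max.col(v, ties.method = "first")
    out[, c] <- v[cbind(seq_len(nrow(v)), am)]
    arg[, c] <- cand[cbind(seq_len(nrow(cand)), am)]
  }
  list(out = out, arg = arg, oh = oh, ow = ow)
}

maxpool2_back <- function(dOut, arg, H, W) {
  C <- ncol(dOut)
  dX <- matrix(0, H * W, C)
  for (c in seq_len(C)) dX[arg[, c], c] <- dOut[, c]
  dX
}

cnn_init <- function(side, channels = 1L, n_classes = 2L,
                     filters = c(8L, 16L, 32L), dense = 32L) {
  layers <- list()
  H <- side; C <- channels
  ks <- c(5L, 3L, 3L)
  for (b in seq_along(filters)) {
    k <- ks[b]; f <- filters[b]
    fan_in <- k * k * C
    layers[[b]] <- list(
      W = matrix(stats::rnorm(fan_in * f, 0, sqrt(2 / fan_in)), fan_in, f),
      b = rep(0, f), k = k,
      ci = NULL, H_in = H, C_in = C)
    H <- (H - k + 1) %/% 2
    C <- f
  }
  flat <- H * H * C
  model <- list(
    conv = layers,
    W1 = matrix(stats::rnorm(flat * dense, 0, sqrt(2 / flat)), flat, dense),
    b1 = rep(0, dense),
    W2 = matrix(stats::rnorm(dense * n_classes, 0, sqrt(2 / dense)), dense, n_classes),
    b2 = rep(0, n_classes),
    side = side, channels = channels, flat = flat)
  # precompute im2col index tables
  H <- side
  for (b in seq_along(model$conv)) {
    k <- model$conv[[b]]$k
    model$conv[[b]]$ci <- conv_index(H, H, k, k)
    model$conv[[b]]$H_in <- H
    H <- (H - k + 1) %/% 2
  }
  model
}

cnn_forward <- function(model, x, keep = FALSE) {
  # x: side x side matrix, already normalised
  X <- matrix(as.vector(x), ncol = 1)
  cache <- list()
  H <- model$side
  for (b in seq_along(model$conv)) {
    ly <- model$conv[[b]]
    P <- im2col(X, ly$ci)
    Z <- P %*% ly$W
    Z <- sweep(Z, 2, ly$b, "+")
    A <- Z * (Z > 0)
    pl <- maxpool2(A, ly$ci$out_h, ly$ci$out_w)
    if (keep) cache[[b]] <- list(X = X, P = P, Z = Z, pl = pl, H = H)
    X <- pl$out
    H <- pl$oh
  }
  v <- as.vector(X)
  h1 <- as.vector(crossprod(model$W1, v)) + model$b1
  a1 <- h1 * (h1 > 0)
  logits <- as.vector(crossprod(model$W2, a1)) + model$b2
  e <- exp(logits - max(logits))
  probs <- e / sum(e)
  if (!keep) return(probs)
  list(probs = probs, cache = cache, v = v, h1 = h1, a1 = a1)
}

cnn_backward <- function(model, fw, y_onehot) {
  g <- list()
  dlogit <- fw$probs - y_onehot
  g$W2 <- outer(fw$a1, dlogit)
  g$b2 <- dlogit
  da1 <- as.vector(model$W2 %*% dlogit)
  dh1 <- da1 * (fw$h1 > 0)
  g$W1 <- outer(fw$v, dh1)
  g$b1 <- dh1
  dX <- matrix(as.vector(model$W1 %*% dh1), ncol = ncol(fw$cache[[length(fw$cache)]]$pl$out))
  g$conv <- vector("list", length(model$conv))
  for (b in rev(seq_along(model$conv))) {
    ly <- model$conv[[b]]
    ca <- fw$cache[[b]]
    dA <- maxpool2_back(dX, ca$pl$arg, ca$H - ly$k + 1, ca$H - ly$k + 1)
    dZ <- dA * (ca$Z > 0)
    g$conv[[b]] <- list(W = crossprod(ca$P, dZ), b = colSums(dZ))
    if (b > 1) {
      dP <- dZ %*% t(ly$W)
      dX <- col2im(dP, ly$ci, ca$H, ca$H, ncol(ca$X))
    }
  }
  g
}

adam_state <- function(model) {
  zero_like <- function(x) { x[] <- 0; x }
  st <- list(t = 0)
  st$W1m <- zero_like(model$W1); st$W1v <- zero_like(model$W1)
  st$b1m <- model$b1 * 0; st$b1v <- model$b1 * 0
  st$W2m <- zero_like(model$W2); st$W2v <- zero_like(model$W2)
  st$b2m <- model$b2 * 0; st$b2v <- model$b2 * 0
  st$conv <- lapply(model$conv, function(ly)
    list(Wm = zero_like(ly$W), Wv = zero_like(ly$W),
         bm = ly$b * 0, bv = ly$b * 0))
  st
}

adam_update <- function(w, g, m, v, t, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  m <- b1 * m + (1 - b1) * g
  v <- b2 * v + (1 - b2) * g^2
  mh <- m / (1 - b1^t); vh <- v / (1 - b2^t)
  list(w = w - lr * mh / (sqrt(vh) + eps), m = m, v = v)
}

cnn_train_step <- function(model, st, x, y_onehot, lr) {
  fw <- cnn_forward(model, x, keep = TRUE)
  g <- cnn_backward(model, fw, y_onehot)
  st$t <- st$t + 1
  up <- adam_update(model$W1, g$W1, st$W1m, st$W1v, st$t, lr)
  model$W1 <- up$w; st$W1m <- up$m; st$W1v <- up$v
  up <- adam_update(model$b1, g$b1, st$b1m, st$b1v, st$t, lr)
  model$b1 <- up$w; st$b1m <- up$m; st$b1v <- up$v
  up <- adam_update(model$W2, g$W2, st$W2m, st$W2v, st$t, lr)
  model$W2 <- up$w; st$W2m <- up$m; st$W2v <- up$v
  up <- adam_update(model$b2, g$b2, st$b2m, st$b2v, st$t, lr)
  model$b2 <- up$w; st$b2m <- up$m; st$b2v <- up$v
  for (b in seq_along(model$conv)) {
    up <- adam_update(model$conv[[b]]$W, g$conv[[b]]$W,
                      st$conv[[b]]$Wm, st$conv[[b]]$Wv, st$t, lr)
    model$conv[[b]]$W <- up$w; st$conv[[b]]$Wm <- up$m; st$conv[[b]]$Wv <- up$v
    up <- adam_update(model$conv[[b]]$b, g$conv[[b]]$b,
                      st$conv[[b]]$bm, st$conv[[b]]$bv, st$t, lr)
    model$conv[[b]]$b <- up$w; st$conv[[b]]$bm <- up$m; st$conv[[b]]$bv <- up$v
  }
  loss <- -log(max(fw$probs[which.max(y_onehot)], 1e-12))
  list(model = model, st = st, loss = loss)
}
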