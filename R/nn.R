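# Minimal neural-network engine for the EMG -> joint-angle regressors.
#
# Three families share an Adam/MSE/early-stopping training loop:
#   dense          multilayer perceptron on the n x width input matrix
#   recurrent      stacked Elman layers over a 20-step trailing window
#   convolutional  3x3 conv blocks over the (20 x width) window image
# Everything is plain matrix algebra (BLAS does the heavy lifting); gradient
# correctness is pinned by numerical-gradient tests on tiny nets.

relu <- function(x) (x + abs(x)) / 2

glorot <- function(nout, nin, gain = 1) {
  matrix(rnorm(nout * nin, sd = gain * sqrt(2 / (nin + nout))), nout, nin)
}

# trailing-window row indices with edge replication: row t sees [t-w+1, t]
seq_row_indices <- function(idx, window) {
  idx <- as.integer(idx)
  window <- as.integer(window)
  m <- vapply(seq_len(window), function(t) pmax(idx - (window - t), 1L),
              integer(length(idx)))  # (batch x window)
  if (is.null(dim(m))) m <- matrix(m, nrow = length(idx))
  m
}

## ---- dense -----------------------------------------------------------------

init_dense <- function(width, hidden, k_out) {
  sizes <- c(width, hidden, k_out)
  p <- list()
  for (l in seq_len(length(sizes) - 1)) {
    p[[paste0("W", l)]] <- glorot(sizes[l + 1], sizes[l])
    p[[paste0("b", l)]] <- numeric(sizes[l + 1])
  }
  attr(p, "n_layers") <- length(sizes) - 1
  p
}

forward_dense <- function(p, X) {
  L <- attr(p, "n_layers")
  A <- vector("list", L + 1)
  A[[1]] <- X
  for (l in seq_len(L)) {
    Z <- A[[l]] %*% t(p[[paste0("W", l)]])
    Z <- sweep(Z, 2, p[[paste0("b", l)]], "+")
    A[[l + 1]] <- if (l < L) relu(Z) else Z
  }
  A
}

backward_dense <- function(p, A, dOut) {
  L <- attr(p, "n_layers")
  g <- list()
  d <- dOut
  for (l in rev(seq_len(L))) {
    g[[paste0("W", l)]] <- t(d) %*% A[[l]]
    g[[paste0("b", l)]] <- colSums(d)
    if (l > 1) d <- (d %*% p[[paste0("W", l)]]) * (A[[l]] > 0)
  }
  g
}

## ---- recurrent (stacked Elman) --------------------------------------------

init_rnn <- function(width, hidden, k_out) {
  stopifnot(length(hidden) >= 1)
  p <- list()
  d_in <- width
  for (l in seq_along(hidden)) {
    h <- hidden[l]
    p[[paste0("W", l)]] <- glorot(h, d_in)
    p[[paste0("U", l)]] <- glorot(h, h, gain = 0.5)
    p[[paste0("b", l)]] <- numeric(h)
    d_in <- h
  }
  p$Wo <- glorot(k_out, d_in)
  p$bo <- numeric(k_out)
  attr(p, "hidden") <- hidden
  p
}

forward_rnn <- function(p, Xseq) {
  # Xseq: list of T matrices (batch x width)
  hidden <- attr(p, "hidden")
  Tn <- length(Xseq)
  b <- nrow(Xseq[[1]])
  H <- lapply(hidden, function(h) vector("list", Tn))
  for (l in seq_along(hidden)) {
    hprev <- matrix(0, b, hidden[l])
    for (t in seq_len(Tn)) {
      inp <- if (l == 1) Xseq[[t]] else H[[l - 1]][[t]]
      Z <- inp %*% t(p[[paste0("W", l)]]) + hprev %*% t(p[[paste0("U", l)]])
      Z <- sweep(Z, 2, p[[paste0("b", l)]], "+")
      H[[l]][[t]] <- tanh(Z)
      hprev <- H[[l]][[t]]
    }
  }
  out <- H[[length(hidden)]][[Tn]] %*% t(p$Wo)
  out <- sweep(out, 2, p$bo, "+")
  list(H = H, out = out)
}

backward_rnn <- function(p, Xseq, fw, dOut) {
  hidden <- attr(p, "hidden")
  L <- length(hidden)
  Tn <- length(Xseq)
  b <- nrow(Xseq[[1]])
  g <- list(Wo = t(dOut) %*% fw$H[[L]][[Tn]], bo = colSums(dOut))
  # dH[[l]][[t]]: gradient wrt hidden state of layer l at step t
  dH <- lapply(hidden, function(h) {
    lapply(seq_len(Tn), function(t) matrix(0, b, h))
  })
  dH[[L]][[Tn]] <- dOut %*% p$Wo
  for (l in rev(seq_len(L))) {
    Wl <- p[[paste0("W", l)]]; Ul <- p[[paste0("U", l)]]
    gW <- matrix(0, nrow(Wl), ncol(Wl)); gU <- matrix(0, nrow(Ul), ncol(Ul))
    gb <- numeric(length(p[[paste0("b", l)]]))
    drec <- matrix(0, b, hidden[l])
    for (t in rev(seq_len(Tn))) {
      d <- dH[[l]][[t]] + drec
      dZ <- d * (1 - fw$H[[l]][[t]]^2)
      inp <- if (l == 1) Xseq[[t]] else fw$H[[l - 1]][[t]]
      gW <- gW + t(dZ) %*% inp
      if (t > 1) gU <- gU + t(dZ) %*% fw$H[[l]][[t - 1]]
      gb <- gb + colSums(dZ)
      if (l > 1) dH[[l - 1]][[t]] <- dH[[l - 1]][[t]] + dZ %*% Wl
      drec <- if (t > 1) dZ %*% Ul else drec * 0
    }
    g[[paste0("W", l)]] <- gW; g[[paste0("U", l)]] <- gU
    g[[paste0("b", l)]] <- gb
  }
  g
}

## ---- convolutional ---------------------------------------------------------

# im2col for batched single/multi-channel images: X array (b, H, W, C)
# returns list(cols = matrix (b*oh*ow, 3*3*C), oh, ow)
im2col3 <- function(X) {
  d <- dim(X); b <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  oh <- H - 2; ow <- W - 2
  if (oh < 1 || ow < 1) abort("feature map too small for a 3x3 convolution")
  cols <- matrix(0, b * oh * ow, 9 * C)
  k <- 0
  for (c in seq_len(C)) for (dj in 0:2) for (di in 0:2) {
    k <- k + 1
    cols[, k] <- as.vector(X[, (1 + di):(oh + di), (1 + dj):(ow + dj), c])
  }
  list(cols = cols, oh = oh, ow = ow, b = b, C = C, H = H, W = W)
}

col2im3 <- function(dcols, meta) {
  dX <- array(0, c(meta$b, meta$H, meta$W, meta$C))
  k <- 0
  for (c in seq_len(meta$C)) for (dj in 0:2) for (di in 0:2) {
    k <- k + 1
    ri <- (1 + di):(meta$oh + di); rj <- (1 + dj):(meta$ow + dj)
    cur <- dX[, ri, rj, c, drop = FALSE]
    dX[, ri, rj, c] <- cur + array(dcols[, k], dim(cur))
  }
  dX
}

# max pooling over non-overlapping (ph x pw) windows of (b, H, W, C)
maxpool <- function(X, ph, pw) {
  d <- dim(X); b <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  oh <- H %/% ph; ow <- W %/% pw
  Xc <- X[, seq_len(oh * ph), seq_len(ow * pw), , drop = FALSE]
  n <- b * oh * ow * C
  cand <- matrix(0, n, ph * pw)
  k <- 0
  for (dj in seq_len(pw)) for (di in seq_len(ph)) {
    k <- k + 1
    cand[, k] <- as.vector(Xc[, seq(di, oh * ph, by = ph),
                              seq(dj, ow * pw, by = pw), , drop = FALSE])
  }
  amax <- max.col(cand, ties.method = "first")
  out <- array(cand[cbind(seq_len(n), amax)], c(b, oh, ow, C))
  list(out = out, argmax = amax, dims = c(b, H, W, C), oh = oh, ow = ow,
       ph = ph, pw = pw)
}

maxpool_backward <- function(dOut, mp) {
  b <- mp$dims[1]; H <- mp$dims[2]; W <- mp$dims[3]; C <- mp$dims[4]
  oh <- mp$oh; ow <- mp$ow; ph <- mp$ph; pw <- mp$pw
  n <- b * oh * ow * C
  dcand <- matrix(0, n, ph * pw)
  dcand[cbind(seq_len(n), mp$argmax)] <- as.vector(dOut)
  dX <- array(0, mp$dims)
  k <- 0
  for (dj in seq_len(pw)) for (di in seq_len(ph)) {
    k <- k + 1
    ri <- seq(di, oh * ph, by = ph); rj <- seq(dj, ow * pw, by = pw)
    cur <- dX[, ri, rj, , drop = FALSE]
    dX[, ri, rj, ] <- cur + array(dcand[, k], dim(cur))
  }
  dX
}

init_conv <- function(width, window, filters, dense_h, k_out, pool = c(2, 4)) {
  stopifnot(length(filters) == 2)
  p <- list(
    K1 = glorot(filters[1], 9),            # filters x (3*3*1)
    c1 = numeric(filters[1]),
    K2 = glorot(filters[2], 9 * filters[1]),
    c2 = numeric(filters[2]))
  p$Wd <- glorot(dense_h, filters[2])
  p$bd <- numeric(dense_h)
  p$Wo <- glorot(k_out, dense_h)
  p$bo <- numeric(k_out)
  attr(p, "pool") <- pool
  p
}

forward_conv <- function(p, X) {
  # X: (b, window, width, 1)
  pool <- attr(p, "pool")
  ic1 <- im2col3(X)
  Z1 <- ic1$cols %*% t(p$K1)
  Z1 <- sweep(Z1, 2, p$c1, "+")
  A1 <- relu(Z1)
  A1a <- array(A1, c(ic1$b, ic1$oh, ic1$ow, nrow(p$K1)))
  mp <- maxpool(A1a, pool[1], pool[2])
  ic2 <- im2col3(mp$out)
  Z2 <- ic2$cols %*% t(p$K2)
  Z2 <- sweep(Z2, 2, p$c2, "+")
  A2 <- relu(Z2)
  A2a <- array(A2, c(ic2$b, ic2$oh, ic2$ow, nrow(p$K2)))
  gap <- apply(A2a, c(1, 4), mean)                  # (b, F2)
  Zd <- sweep(gap %*% t(p$Wd), 2, p$bd, "+")
  Ad <- relu(Zd)
  out <- sweep(Ad %*% t(p$Wo), 2, p$bo, "+")
  list(ic1 = ic1, A1 = A1, mp = mp, ic2 = ic2, A2 = A2,
       a2dim = c(ic2$b, ic2$oh, ic2$ow, nrow(p$K2)),
       gap = gap, Ad = Ad, out = out)
}

backward_conv <- function(p, fw, dOut) {
  g <- list(Wo = t(dOut) %*% fw$Ad, bo = colSums(dOut))
  dAd <- (dOut %*% p$Wo) * (fw$Ad > 0)
  g$Wd <- t(dAd) %*% fw$gap
  g$bd <- colSums(dAd)
  dgap <- dAd %*% p$Wd                              # (b, F2)
  b <- fw$a2dim[1]; oh <- fw$a2dim[2]; ow <- fw$a2dim[3]; F2 <- fw$a2dim[4]
  dA2a <- array(0, fw$a2dim)
  for (c in seq_len(F2)) dA2a[, , , c] <- array(rep(dgap[, c] / (oh * ow), oh * ow),
                                                c(b, oh, ow))
  dA2 <- matrix(as.vector(dA2a), b * oh * ow, F2) * (fw$A2 > 0)
  g$K2 <- t(dA2) %*% fw$ic2$cols
  g$c2 <- colSums(dA2)
  dcols2 <- dA2 %*% p$K2
  dPool <- col2im3(dcols2, fw$ic2)
  dA1a <- maxpool_backward(dPool, fw$mp)
  F1 <- nrow(p$K1)
  dA1 <- matrix(as.vector(dA1a), fw$ic1$b * fw$ic1$oh * fw$ic1$ow, F1) * (fw$A1 > 0)
  g$K1 <- t(dA1) %*% fw$ic1$cols
  g$c1 <- colSums(dA1)
  g
}

## ---- shared training loop --------------------------------------------------

adam_step <- function(p, g, state, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(g)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    p[[nm]] <- p[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(p = p, state = state)
}

build_batch_input <- function(family, Xs, idx, window) {
  if (family == "dense") return(Xs[idx, , drop = FALSE])
  rows <- seq_row_indices(idx, window)
  if (family == "recurrent") {
    lapply(seq_len(window), function(t) Xs[rows[, t], , drop = FALSE])
  } else {
    X <- array(0, c(length(idx), window, ncol(Xs), 1))
    for (t in seq_len(window)) X[, t, , 1] <- Xs[rows[, t], , drop = FALSE]
    X
  }
}

net_forward_out <- function(family, p, Xb) {
  switch(family,
         dense = {A <- forward_dense(p, Xb); list(fw = A, out = A[[length(A)]])},
         recurrent = {fw <- forward_rnn(p, Xb); list(fw = fw, out = fw$out)},
         convolutional = {fw <- forward_conv(p, Xb); list(fw = fw, out = fw$out)})
}

net_backward <- function(family, p, Xb, fw, dOut) {
  switch(family,
         dense = backward_dense(p, fw, dOut),
         recurrent = backward_rnn(p, Xb, fw, dOut),
         convolutional = backward_conv(p, fw, dOut))
}

# predictions for arbitrary row indices, in memory-bounded chunks
net_predict <- function(family, p, Xs, idx, window, chunk = 2048L) {
  out <- matrix(0, length(idx), length(if (is.null(p$bo)) p[[paste0("b", attr(p, "n_layers"))]] else p$bo))
  s <- 1L
  while (s <= length(idx)) {
    e <- min(length(idx), s + chunk - 1L)
    Xb <- build_batch_input(family, Xs, idx[s:e], window)
    out[s:e, ] <- net_forward_out(family, p, Xb)$out
    s <- e + 1L
  }
  out
}

fit_net <- function(family, Xs, Ys, train_idx, val_idx, cfg) {
  set.seed(derive_seed(cfg$seed, 0))
  width <- ncol(Xs); k_out <- ncol(Ys)
  p <- switch(family,
    dense = init_dense(width, cfg$layers, k_out),
    recurrent = init_rnn(width, cfg$layers, k_out),
    convolutional = init_conv(width, cfg$window, cfg$filters, cfg$dense_units,
                              k_out, cfg$pool))
  state <- list(m = lapply(p, function(x) x * 0), v = lapply(p, function(x) x * 0))
  best <- list(loss = Inf, p = p, epoch = 0)
  log <- list()
  tglob <- 0
  wait <- 0
  for (epoch in seq_len(cfg$epochs)) {
    set.seed(derive_seed(cfg$seed, epoch))
    ord <- sample(train_idx)
    tr_loss <- 0; nb <- 0
    for (s in seq(1, length(ord), by = cfg$batch_size)) {
      idx <- ord[s:min(length(ord), s + cfg$batch_size - 1)]
      Xb <- build_batch_input(family, Xs, idx, cfg$window)
      Yb <- Ys[idx, , drop = FALSE]
      f <- net_forward_out(family, p, Xb)
      err <- f$out - Yb
      loss <- mean(err^2)
      if (!is.finite(loss)) abort("non-finite training loss: aborting fit")
      dOut <- 2 * err / length(err)
      g <- net_backward(family, p, Xb, f$fw, dOut)
      tglob <- tglob + 1
      upd <- adam_step(p, g, state, cfg$learning_rate, tglob)
      p <- upd$p; state <- upd$state
      tr_loss <- tr_loss + loss; nb <- nb + 1
    }
    val_pred <- net_predict(family, p, Xs, val_idx, cfg$window)
    val_loss <- mean((val_pred - Ys[val_idx, , drop = FALSE])^2)
    log[[epoch]] <- c(epoch = epoch, train_loss = tr_loss / nb, val_loss = val_loss)
    if (val_loss < best$loss - 1e-12) {
      best <- list(loss = val_loss, p = p, epoch = epoch)
      wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= cfg$patience) break
    }
  }
  list(params = best$p, best_epoch = best$epoch, best_val = best$loss,
       log = tibble::as_tibble(do.call(rbind, log)))
}
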