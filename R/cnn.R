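# Minimal 1D convolutional network for spectra, written with vectorised
# matrix products: stacked valid-convolution blocks (conv -> ReLU -> max-pool
# except after the last block), flatten, dropout, and a dense softmax head,
# trained by Adam on the cross-entropy. The flattened (not globally pooled)
# head is deliberate: class-differential Raman bands are distinguished by
# their position on the wavenumber axis, which pooling over positions would
# erase. Gradients are exact (verified against finite differences in the
# test suite).

cnn_defaults <- function() {
  list(learning_rate = 1e-3, epochs = 30, batch_size = 32,
       channels = c(8, 16, 32), kernel_sizes = c(9, 7, 5),
       pool = 2, dropout = 0)
}

cnn_out_length <- function(L, hp) {
  nb <- length(hp$channels)
  for (i in seq_len(nb)) {
    L <- L - hp$kernel_sizes[i] + 1
    if (i < nb) L <- L %/% hp$pool
    if (L < 1) return(0L)
  }
  L
}

# X: (B, L, Cin) array; W: (k, Cin, Cout); b: length Cout
conv1d_forward <- function(X, W, b) {
  d <- dim(X); B <- d[1]; Cin <- d[3]
  k <- dim(W)[1]; Cout <- dim(W)[3]
  Lout <- d[2] - k + 1
  Y <- matrix(rep(b, each = B * Lout), B * Lout, Cout)
  for (j in seq_len(k)) {
    Xs <- X[, j:(j + Lout - 1), , drop = FALSE]
    dim(Xs) <- c(B * Lout, Cin)
    Y <- Y + Xs %*% matrix(W[j, , ], Cin, Cout)
  }
  dim(Y) <- c(B, Lout, Cout)
  Y
}

conv1d_backward <- function(X, W, dY) {
  d <- dim(X); B <- d[1]; Cin <- d[3]
  k <- dim(W)[1]; Cout <- dim(W)[3]
  Lout <- dim(dY)[2]
  dYm <- dY; dim(dYm) <- c(B * Lout, Cout)
  dW <- array(0, dim(W))
  dX <- array(0, d)
  for (j in seq_len(k)) {
    Xs <- X[, j:(j + Lout - 1), , drop = FALSE]
    dim(Xs) <- c(B * Lout, Cin)
    dW[j, , ] <- crossprod(Xs, dYm)
    dXs <- dYm %*% t(matrix(W[j, , ], Cin, Cout))
    dim(dXs) <- c(B, Lout, Cin)
    dX[, j:(j + Lout - 1), ] <- dX[, j:(j + Lout - 1), , drop = FALSE] + dXs
  }
  list(dX = dX, dW = dW, db = colSums(dYm))
}

pool2_forward <- function(X) {
  d <- dim(X); Lp <- d[2] %/% 2L
  io <- seq(1L, 2L * Lp, by = 2L)
  A <- X[, io, , drop = FALSE]
  B2 <- X[, io + 1L, , drop = FALSE]
  m <- A >= B2
  Y <- A
  Y[!m] <- B2[!m]
  list(Y = Y, mask = m, Lin = d[2])
}

pool2_backward <- function(dY, mask, Lin) {
  d <- dim(dY)
  dX <- array(0, c(d[1], Lin, d[3]))
  io <- seq(1L, 2L * d[2], by = 2L)
  dX[, io, ] <- dY * mask
  dX[, io + 1L, ] <- dY * !mask
  dX
}

cnn_init <- function(L, n_classes, hp) {
  nb <- length(hp$channels)
  cin <- 1L
  params <- list()
  for (i in seq_len(nb)) {
    k <- hp$kernel_sizes[i]; cout <- hp$channels[i]
    params[[paste0("Wc", i)]] <-
      array(stats::rnorm(k * cin * cout, 0, sqrt(2 / (k * cin))), c(k, cin, cout))
    params[[paste0("bc", i)]] <- numeric(cout)
    cin <- cout
  }
  nfeat <- cnn_out_length(L, hp) * cin
  params$Wd <- matrix(stats::rnorm(nfeat * n_classes, 0, sqrt(2 / nfeat)),
                      nfeat, n_classes)
  params$bd <- numeric(n_classes)
  params
}

# Forward pass to class probabilities. X: (B, L) matrix.
cnn_forward_probs <- function(params, X, hp) {
  nb <- length(hp$channels)
  A <- array(X, c(nrow(X), ncol(X), 1L))
  for (i in seq_len(nb)) {
    A <- conv1d_forward(A, params[[paste0("Wc", i)]], params[[paste0("bc", i)]])
    A[A < 0] <- 0
    if (i < nb) A <- pool2_forward(A)$Y
  }
  G <- A
  dim(G) <- c(dim(A)[1], dim(A)[2] * dim(A)[3])
  logits <- G %*% params$Wd + rep(params$bd, each = nrow(G))
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Loss and exact gradients for one batch. yidx: integer classes in 1..C.
# keep: optional dropout keep-mask (B x C_last), already inverted-scaled.
cnn_loss_grad <- function(params, X, yidx, hp, keep = NULL) {
  nb <- length(hp$channels)
  B <- nrow(X)
  A <- array(X, c(B, ncol(X), 1L))
  caches <- vector("list", nb)
  for (i in seq_len(nb)) {
    pre <- conv1d_forward(A, params[[paste0("Wc", i)]], params[[paste0("bc", i)]])
    rl <- pre > 0
    act <- pre * rl
    if (i < nb) {
      pl <- pool2_forward(act)
      caches[[i]] <- list(X = A, relu = rl, mask = pl$mask, Lin = pl$Lin)
      A <- pl$Y
    } else {
      caches[[i]] <- list(X = A, relu = rl)
      A <- act
    }
  }
  dg <- dim(A)
  G <- A
  dim(G) <- c(dg[1], dg[2] * dg[3])
  if (!is.null(keep)) G <- G * keep
  logits <- G %*% params$Wd + rep(params$bd, each = B)
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  probs <- e / rowSums(e)
  picked <- probs[cbind(seq_len(B), yidx)]
  loss <- -mean(log(pmax(picked, 1e-15)))
  dlogits <- probs
  dlogits[cbind(seq_len(B), yidx)] <- dlogits[cbind(seq_len(B), yidx)] - 1
  dlogits <- dlogits / B
  grads <- list(Wd = crossprod(G, dlogits), bd = colSums(dlogits))
  dG <- dlogits %*% t(params$Wd)
  if (!is.null(keep)) dG <- dG * keep
  dA <- dG
  dim(dA) <- dg
  for (i in rev(seq_len(nb))) {
    cc <- caches[[i]]
    if (i < nb) dA <- pool2_backward(dA, cc$mask, cc$Lin)
    dA <- dA * cc$relu
    bk <- conv1d_backward(cc$X, params[[paste0("Wc", i)]], dA)
    grads[[paste0("Wc", i)]] <- bk$dW
    grads[[paste0("bc", i)]] <- bk$db
    dA <- bk$dX
  }
  list(loss = loss, grads = grads)
}

cnn_fit <- function(X, yidx, n_classes, hp, seed) {
  set.seed(seed)
  L <- ncol(X)
  if (cnn_out_length(L, hp) < 1L)
    stop("spectra too short (", L, " channels) for the CNN architecture")
  n <- nrow(X)
  params <- cnn_init(L, n_classes, hp)
  m <- lapply(params, function(p) p * 0)
  v <- m
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  t <- 0L
  nfeat <- cnn_out_length(L, hp) * hp$channels[length(hp$channels)]
  for (epoch in seq_len(hp$epochs)) {
    ord <- sample.int(n)
    nb_batch <- ceiling(n / hp$batch_size)
    for (bi in seq_len(nb_batch)) {
      idx <- ord[((bi - 1L) * hp$batch_size + 1L):min(bi * hp$batch_size, n)]
      keep <- NULL
      if (hp$dropout > 0) {
        keep <- matrix(stats::rbinom(length(idx) * nfeat, 1L, 1 - hp$dropout),
                       length(idx), nfeat) / (1 - hp$dropout)
      }
      lg <- cnn_loss_grad(params, X[idx, , drop = FALSE], yidx[idx], hp, keep)
      t <- t + 1L
      for (nm in names(params)) {
        g <- lg$grads[[nm]]
        m[[nm]] <- b1 * m[[nm]] + (1 - b1) * g
        v[[nm]] <- b2 * v[[nm]] + (1 - b2) * g^2
        mhat <- m[[nm]] / (1 - b1^t)
        vhat <- v[[nm]] / (1 - b2^t)
        params[[nm]] <- params[[nm]] - hp$learning_rate * mhat / (sqrt(vhat) + eps)
      }
    }
  }
  list(params = params, hp = hp, n_classes = n_classes, input_length = L)
}

cnn_predict <- function(fit, X, chunk = 256L) {
  if (ncol(X) != fit$input_length)
    stop("input has ", ncol(X), " channels; CNN was trained on ",
         fit$input_length)
  n <- nrow(X)
  out <- matrix(0, n, fit$n_classes)
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    out[i:j, ] <- cnn_forward_probs(fit$params, X[i:j, , drop = FALSE], fit$hp)
    i <- j + 1L
  }
  out
}
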