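# Low-level differentiable layers for the SENN backbone.
#
# Batch tensors are stored as arrays with dim (T, B, C): time-major so that a
# temporal shift is a contiguous row slice shared by all samples and channels.
# 1-D convolution is expressed as a single BLAS gemm on an im2col buffer that
# is cached in the forward pass and reused for the weight/input gradients.

as_tbc <- function(x) {
  # (B, T, C) array -> (T, B, C)
  aperm(x, c(2L, 1L, 3L))
}

# Memoised gather indices for im2col, keyed by the (T, B, C, k) signature.
.im2col_idx <- new.env(parent = emptyenv())

im2col_indices <- function(Tn, B, Cin, k) {
  key <- paste(Tn, B, Cin, k, sep = "_")
  idx <- .im2col_idx[[key]]
  if (is.null(idx)) {
    pad <- (k - 1L) %/% 2L
    # element (t, b | ci, dlt) of the (Tn*B) x (Cin*k) buffer reads the
    # input at time s = t + dlt - 1 - pad; out-of-range positions point at a
    # zero sentinel appended after the input
    sv <- rep(seq_len(Tn), times = B * Cin * k) +
      rep(seq_len(k) - 1L - pad, each = Tn * B * Cin)
    idx <- sv +
      rep(rep((seq_len(B) - 1L) * Tn, each = Tn), times = Cin * k) +
      rep(rep((seq_len(Cin) - 1L) * (Tn * B), each = Tn * B), times = k)
    idx[sv < 1L | sv > Tn] <- Tn * B * Cin + 1L
    .im2col_idx[[key]] <- idx
  }
  idx
}

# im2col: (T, B, Cin) array -> (T*B, Cin*k) matrix ('same' zero padding)
im2col <- function(x, k) {
  d <- dim(x)
  X2 <- c(x, 0)[im2col_indices(d[1L], d[2L], d[3L], k)]
  dim(X2) <- c(d[1L] * d[2L], d[3L] * k)
  X2
}

#' @noRd
conv1d_forward <- function(x, W, b, cache = FALSE) {
  d <- dim(x)
  Tn <- d[1L]; B <- d[2L]; Cin <- d[3L]
  k <- dim(W)[1L]; Cout <- dim(W)[3L]
  stopifnot(dim(W)[2L] == Cin, k %% 2L == 1L)
  if (k == 1L) {
    X2 <- x
    dim(X2) <- c(Tn * B, Cin)
  } else {
    X2 <- im2col(x, k)
  }
  Wm <- matrix(aperm(W, c(2L, 1L, 3L)), Cin * k, Cout)
  y <- X2 %*% Wm
  y <- y + rep(b, each = Tn * B)
  dim(y) <- c(Tn, B, Cout)
  if (cache) list(y = y, X2 = X2) else y
}

#' @noRd
conv1d_backward <- function(dy, X2, W, Tn, B) {
  k <- dim(W)[1L]; Cin <- dim(W)[2L]; Cout <- dim(W)[3L]
  dym <- dy
  dim(dym) <- c(Tn * B, Cout)
  dWm <- crossprod(X2, dym)                       # (Cin*k) x Cout
  dW <- aperm(array(dWm, c(Cin, k, Cout)), c(2L, 1L, 3L))
  db <- colSums(dym)
  if (k == 1L) {
    Wm <- matrix(W, Cin, Cout)
    dx <- tcrossprod(dym, Wm)
    dim(dx) <- c(Tn, B, Cin)
  } else {
    # dx is the convolution of dy with the time-flipped, transposed kernel
    dyarr <- dym
    dim(dyarr) <- c(Tn, B, Cout)
    dY2 <- im2col(dyarr, k)                       # (Tn*B) x (Cout*k)
    Wf <- aperm(W[k:1, , , drop = FALSE], c(3L, 1L, 2L))
    dx <- dY2 %*% matrix(Wf, Cout * k, Cin)
    dim(dx) <- c(Tn, B, Cin)
  }
  list(dx = dx, dW = dW, db = db)
}

# Batch normalisation over the (T, B) axes, one statistic per channel.
#' @noRd
batchnorm_forward <- function(x, gamma, beta, running_mean, running_var,
                              eps, momentum, training, update_running = TRUE) {
  d <- dim(x)
  N <- d[1L] * d[2L]; C <- d[3L]
  xm <- x
  dim(xm) <- c(N, C)
  if (training) {
    mu <- colMeans(xm)
    xc <- xm - rep(mu, each = N)
    va <- colMeans(xc * xc)
    if (update_running) {
      running_mean <- (1 - momentum) * running_mean + momentum * mu
      running_var <- (1 - momentum) * running_var + momentum * va
    }
  } else {
    mu <- running_mean
    va <- running_var
    xc <- xm - rep(mu, each = N)
  }
  invstd <- 1 / sqrt(va + eps)
  xhat <- xc * rep(invstd, each = N)
  y <- xhat * rep(gamma, each = N) + rep(beta, each = N)
  dim(y) <- d
  list(y = y, cache = list(xhat = xhat, invstd = invstd, dims = d),
       running_mean = running_mean, running_var = running_var)
}

#' @noRd
batchnorm_backward <- function(dy, gamma, cache) {
  d <- cache$dims
  N <- d[1L] * d[2L]
  dym <- dy
  dim(dym) <- c(N, d[3L])
  xhat <- cache$xhat
  dgamma <- colSums(dym * xhat)
  dbeta <- colSums(dym)
  # dx = gamma*invstd/N * (N*dy - sum(dy) - xhat * sum(dy*xhat))
  dx <- (N * dym - rep(dbeta, each = N) - xhat * rep(dgamma, each = N)) *
    rep(gamma * cache$invstd / N, each = N)
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# Layer normalisation across the feature (last) dimension of a B x K matrix.
#' @noRd
layernorm_forward <- function(x, gamma, beta, eps) {
  mu <- rowMeans(x)
  xc <- x - mu
  va <- rowMeans(xc * xc)
  invstd <- 1 / sqrt(va + eps)
  xhat <- xc * invstd
  y <- sweep(xhat, 2L, gamma, "*")
  y <- sweep(y, 2L, beta, "+")
  list(y = y, cache = list(xhat = xhat, invstd = invstd))
}

#' @noRd
layernorm_backward <- function(dy, gamma, cache) {
  xhat <- cache$xhat
  K <- ncol(xhat)
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2L, gamma, "*")
  rs <- rowSums(dxhat)
  rsx <- rowSums(dxhat * xhat)
  dx <- (dxhat - rs / K - xhat * rsx / K) * cache$invstd
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

#' @noRd
maxpool2_forward <- function(x) {
  d <- dim(x)
  stopifnot(d[1L] %% 2L == 0L)
  i1 <- seq.int(1L, d[1L], 2L)
  x1 <- x[i1, , , drop = FALSE]
  x2 <- x[i1 + 1L, , , drop = FALSE]
  take_first <- x1 >= x2
  y <- pmax(x1, x2)
  dim(y) <- c(d[1L] %/% 2L, d[2L], d[3L])
  list(y = y, cache = list(take_first = take_first, dims = d))
}

#' @noRd
maxpool2_backward <- function(dy, cache) {
  d <- cache$dims
  dx <- array(0, d)
  i1 <- seq.int(1L, d[1L], 2L)
  tf <- cache$take_first
  storage.mode(tf) <- "double"
  dim(tf) <- dim(dy)
  dx[i1, , ] <- dy * tf
  dx[i1 + 1L, , ] <- dy * (1 - tf)
  dx
}

# Inverted dropout masks: scaling happens at train time so evaluation is the
# identity map.
#' @noRd
dropout_mask <- function(dims, rate) {
  if (rate <= 0) return(NULL)
  m <- array(stats::runif(prod(dims)) >= rate, dims)
  storage.mode(m) <- "double"
  m / (1 - rate)
}

# Spatial dropout: one Bernoulli per (sample, channel), broadcast along time.
#' @noRd
spatial_dropout_mask <- function(Tn, B, C, rate) {
  if (rate <= 0) return(NULL)
  m <- matrix(stats::runif(B * C) >= rate, B, C)
  storage.mode(m) <- "double"
  m <- m / (1 - rate)
  array(rep(m, each = Tn), c(Tn, B, C))
}

#' @noRd
sigmoid <- function(x) 1 / (1 + exp(-x))
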