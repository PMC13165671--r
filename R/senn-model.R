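#' SENN architecture configuration
#'
#' Hyperparameters of the self-explaining network: a four-block residual 1-D
#' convolutional backbone with stochastic depth, a tanh + layer-norm concept
#' encoder producing `K` concept activations, an MLP relevance network, and a
#' scalar-aggregate classification head. Defaults reproduce the study
#' configuration for 128-timestep, 16-channel ground-reaction-force windows.
#'
#' @param K Number of learned concepts.
#' @param filters Convolution filter counts for the four residual blocks.
#' @param kernel_size Temporal kernel width of the backbone convolutions
#'   ('same' padding; must be odd).
#' @param p_L Maximum stochastic-depth drop probability, assigned to the
#'   deepest block by the linear schedule (see [stochastic_depth_schedule()]).
#' @param spatial_dropout Channel-wise dropout rate inside residual blocks.
#' @param gap_dropout Dropout rate after global average pooling.
#' @param dense_dropout Dropout rate in the relevance network and head.
#' @param l2 L2 penalty coefficient on convolutional kernels (added to the
#'   loss; distinct from the optimiser's decoupled weight decay).
#' @param lambda_div,lambda_spar,lambda_stab Coefficients of the diversity,
#'   sparsity and stability regularisers.
#' @param label_smoothing Label-smoothing factor of the binary cross-entropy.
#' @param window,input_channels Expected window length and channel count.
#'   `window` must be divisible by 8 (three max-pools of 2).
#' @param relevance_units Hidden sizes of the relevance MLP.
#' @param head_units Width of the hidden head layer applied to the scalar
#'   aggregate.
#' @param layernorm_eps,bn_eps,bn_momentum Numerical constants of the
#'   normalisation layers.
#' @return An object of class `senn_config` (a named list).
#' @export
senn_config <- function(K = 16L, filters = c(32L, 64L, 128L, 128L),
                        kernel_size = 5L, p_L = 0.15,
                        spatial_dropout = 0.15, gap_dropout = 0.22,
                        dense_dropout = 0.45, l2 = 3e-4,
                        lambda_div = 1e-3, lambda_spar = 2e-4,
                        lambda_stab = 5e-4, label_smoothing = 0.05,
                        window = 128L, input_channels = 16L,
                        relevance_units = c(64L, 32L), head_units = 16L,
                        layernorm_eps = 1e-5, bn_eps = 1e-3,
                        bn_momentum = 0.1) {
  stopifnot(K >= 1L, length(filters) == 4L, kernel_size %% 2L == 1L,
            p_L >= 0, p_L < 1, window %% 8L == 0L,
            all(c(spatial_dropout, gap_dropout, dense_dropout) >= 0),
            all(c(spatial_dropout, gap_dropout, dense_dropout) < 1),
            all(c(lambda_div, lambda_spar, lambda_stab, l2) >= 0),
            label_smoothing >= 0, label_smoothing < 1,
            length(relevance_units) == 2L)
  structure(list(
    K = as.integer(K), filters = as.integer(filters),
    kernel_size = as.integer(kernel_size), p_L = p_L,
    spatial_dropout = spatial_dropout, gap_dropout = gap_dropout,
    dense_dropout = dense_dropout, l2 = l2,
    lambda_div = lambda_div, lambda_spar = lambda_spar,
    lambda_stab = lambda_stab, label_smoothing = label_smoothing,
    window = as.integer(window), input_channels = as.integer(input_channels),
    relevance_units = as.integer(relevance_units),
    head_units = as.integer(head_units),
    layernorm_eps = layernorm_eps, bn_eps = bn_eps,
    bn_momentum = bn_momentum
  ), class = "senn_config")
}

#' Linear stochastic-depth schedule
#'
#' Per-block drop probabilities `p_i = ((i - 1) / (L - 1)) * p_L` for a
#' residual network of `L` blocks: the first block is never dropped and the
#' deepest block is dropped at the maximum rate `p_L`.
#'
#' @param L Number of residual blocks (at least 2).
#' @param p_L Maximum drop probability in `[0, 1)`.
#' @return Numeric vector of length `L` of drop probabilities.
#' @examples
#' stochastic_depth_schedule(4, 0.15) # 0.00 0.05 0.10 0.15
#' @export
stochastic_depth_schedule <- function(L, p_L) {
  if (!is.numeric(L) || length(L) != 1L || L < 2L) {
    stop("`L` must be a single integer >= 2 (the schedule divides by L - 1).",
         call. = FALSE)
  }
  if (!is.numeric(p_L) || p_L < 0 || p_L >= 1) {
    stop("`p_L` must lie in [0, 1).", call. = FALSE)
  }
  L <- as.integer(L)
  (seq_len(L) - 1) / (L - 1) * p_L
}

glorot_mat <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

he_conv <- function(k, cin, cout) {
  sd <- sqrt(2 / (k * cin))
  array(stats::rnorm(k * cin * cout, 0, sd), c(k, cin, cout))
}

#' Initialise SENN parameters
#'
#' Draws fresh parameters for every layer: He-normal convolution kernels,
#' Glorot-uniform dense weights, unit batch-norm/layer-norm scales. Consumes
#' the R random stream, so wrap in `set.seed()` for reproducibility.
#'
#' @param config A [senn_config()].
#' @return List with `params` (trainable arrays, flat named list) and `state`
#'   (batch-norm running statistics).
#' @export
senn_init <- function(config) {
  stopifnot(inherits(config, "senn_config"))
  k <- config$kernel_size
  cins <- c(config$input_channels, config$filters[-4L])
  params <- list()
  state <- list()
  for (i in 1:4) {
    f <- config$filters[i]
    cin <- cins[i]
    pfx <- paste0("block", i, ".")
    params[[paste0(pfx, "conv1.W")]] <- he_conv(k, cin, f)
    params[[paste0(pfx, "conv1.b")]] <- numeric(f)
    params[[paste0(pfx, "bn1.gamma")]] <- rep(1, f)
    params[[paste0(pfx, "bn1.beta")]] <- numeric(f)
    params[[paste0(pfx, "conv2.W")]] <- he_conv(k, f, f)
    params[[paste0(pfx, "conv2.b")]] <- numeric(f)
    params[[paste0(pfx, "bn2.gamma")]] <- rep(1, f)
    params[[paste0(pfx, "bn2.beta")]] <- numeric(f)
    if (cin != f) {
      params[[paste0(pfx, "proj.W")]] <- he_conv(1L, cin, f)
      params[[paste0(pfx, "proj.b")]] <- numeric(f)
    }
    state[[paste0(pfx, "bn1.mean")]] <- numeric(f)
    state[[paste0(pfx, "bn1.var")]] <- rep(1, f)
    state[[paste0(pfx, "bn2.mean")]] <- numeric(f)
    state[[paste0(pfx, "bn2.var")]] <- rep(1, f)
  }
  feat <- config$filters[4L]
  K <- config$K
  r1 <- config$relevance_units[1L]
  r2 <- config$relevance_units[2L]
  hu <- config$head_units
  params[["concept.W"]] <- glorot_mat(feat, K)
  params[["concept.b"]] <- numeric(K)
  params[["concept.ln.gamma"]] <- rep(1, K)
  params[["concept.ln.beta"]] <- numeric(K)
  params[["relevance.W1"]] <- glorot_mat(feat, r1)
  params[["relevance.b1"]] <- numeric(r1)
  params[["relevance.W2"]] <- glorot_mat(r1, r2)
  params[["relevance.b2"]] <- numeric(r2)
  params[["relevance.W3"]] <- glorot_mat(r2, K)
  params[["relevance.b3"]] <- numeric(K)
  params[["relevance.ln.gamma"]] <- rep(1, K)
  params[["relevance.ln.beta"]] <- numeric(K)
  params[["head.W4"]] <- matrix(stats::runif(hu, -1, 1) * sqrt(6 / (1 + hu)), 1L, hu)
  params[["head.b4"]] <- numeric(hu)
  params[["head.W5"]] <- glorot_mat(hu, 1L)
  params[["head.b5"]] <- numeric(1L)
  list(params = params, state = state)
}

#' Forward pass of the SENN
#'
#' Computes, for a batch of standardised windows, the pooled backbone feature
#' `x_gap`, raw and layer-normalised concept activations `h` / `h_tilde`,
#' relevance scores `theta`, the scalar aggregate
#' `z = sum_k h_tilde_k * theta_k` (the structural explanation identity), and
#' the PD probability `y_hat`. In `train` mode, dropout, spatial dropout and
#' stochastic depth are sampled from the R random stream and batch-norm uses
#' (and updates) batch statistics; in `eval` mode the pass is deterministic.
#'
#' @param params,state From [senn_init()] (or a trained model).
#' @param x Windows, array `B x T x C` (or `T x B x C` if
#'   `time_major = TRUE`).
#' @param config A [senn_config()].
#' @param train Logical; training mode.
#' @param keep_cache Keep intermediate activations for backpropagation.
#' @param time_major Set if `x` is already time-major.
#' @return List with elements `x_gap` (B x feat), `h`, `h_tilde`, `theta`
#'   (B x K), `z`, `y_hat` (length B), updated `state`, and (optionally)
#'   `cache`.
#' @export
senn_forward <- function(params, state, x, config, train = FALSE,
                         keep_cache = FALSE, time_major = FALSE) {
  stopifnot(inherits(config, "senn_config"))
  if (!time_major) x <- as_tbc(x)
  d <- dim(x)
  if (d[1L] != config$window || d[3L] != config$input_channels) {
    stop(sprintf("input dims (T=%d, C=%d) do not match config (T=%d, C=%d)",
                 d[1L], d[3L], config$window, config$input_channels),
         call. = FALSE)
  }
  B <- d[2L]
  sched <- stochastic_depth_schedule(4L, config$p_L)
  cache <- list(blocks = vector("list", 4L))
  cur <- x
  for (i in 1:4) {
    pfx <- paste0("block", i, ".")
    bc <- list()
    dropped <- train && sched[i] > 0 && stats::runif(1L) < sched[i]
    # skip path (1x1 projection when channel counts change)
    if (!is.null(params[[paste0(pfx, "proj.W")]])) {
      skip <- conv1d_forward(cur, params[[paste0(pfx, "proj.W")]],
                             params[[paste0(pfx, "proj.b")]])
    } else {
      skip <- cur
    }
    if (dropped) {
      out <- skip
      bc$dropped <- TRUE
      bc$x_in <- if (keep_cache) cur else NULL
    } else {
      cv1 <- conv1d_forward(cur, params[[paste0(pfx, "conv1.W")]],
                            params[[paste0(pfx, "conv1.b")]],
                            cache = keep_cache)
      c1 <- if (keep_cache) cv1$y else cv1
      bn1 <- batchnorm_forward(c1, params[[paste0(pfx, "bn1.gamma")]],
                               params[[paste0(pfx, "bn1.beta")]],
                               state[[paste0(pfx, "bn1.mean")]],
                               state[[paste0(pfx, "bn1.var")]],
                               config$bn_eps, config$bn_momentum,
                               training = train, update_running = train)
      state[[paste0(pfx, "bn1.mean")]] <- bn1$running_mean
      state[[paste0(pfx, "bn1.var")]] <- bn1$running_var
      a1 <- bn1$y
      relu1 <- (a1 > 0) * 1
      a1 <- a1 * relu1
      sd_mask <- if (train) {
        spatial_dropout_mask(dim(a1)[1L], B, dim(a1)[3L], config$spatial_dropout)
      } else NULL
      a1d <- if (is.null(sd_mask)) a1 else a1 * sd_mask
      cv2 <- conv1d_forward(a1d, params[[paste0(pfx, "conv2.W")]],
                            params[[paste0(pfx, "conv2.b")]],
                            cache = keep_cache)
      c2 <- if (keep_cache) cv2$y else cv2
      bn2 <- batchnorm_forward(c2, params[[paste0(pfx, "bn2.gamma")]],
                               params[[paste0(pfx, "bn2.beta")]],
                               state[[paste0(pfx, "bn2.mean")]],
                               state[[paste0(pfx, "bn2.var")]],
                               config$bn_eps, config$bn_momentum,
                               training = train, update_running = train)
      state[[paste0(pfx, "bn2.mean")]] <- bn2$running_mean
      state[[paste0(pfx, "bn2.var")]] <- bn2$running_var
      pre <- bn2$y + skip
      relu_out <- (pre > 0) * 1
      out <- pre * relu_out
      if (keep_cache) {
        bc <- list(dropped = FALSE, x_in = cur, X2_1 = cv1$X2,
                   bn1 = bn1$cache, relu1 = relu1, sd_mask = sd_mask,
                   X2_2 = cv2$X2, bn2 = bn2$cache, relu_out = relu_out)
      }
    }
    if (i < 4L) {
      mp <- maxpool2_forward(out)
      out <- mp$y
      if (keep_cache) bc$pool <- mp$cache
    }
    if (keep_cache) cache$blocks[[i]] <- bc
    cur <- out
  }
  # global average pooling over the remaining temporal positions
  Tp <- dim(cur)[1L]
  feat <- dim(cur)[3L]
  curm <- cur
  dim(curm) <- c(Tp, B * feat)
  gap <- matrix(colMeans(curm), B, feat)
  gap_mask <- if (train) dropout_mask(c(B, feat), config$gap_dropout) else NULL
  x_gap <- if (is.null(gap_mask)) gap else gap * gap_mask

  # concept encoder: tanh affine, then layer-norm over the K concepts
  h_pre <- sweep(x_gap %*% params$concept.W, 2L, params$concept.b, "+")
  h <- tanh(h_pre)
  ln_h <- layernorm_forward(h, params$concept.ln.gamma, params$concept.ln.beta,
                            config$layernorm_eps)
  h_tilde <- ln_h$y

  # relevance network: 128 -> 64 -> 32 -> K with ReLU + dropout, layer-norm
  a_pre <- sweep(x_gap %*% params$relevance.W1, 2L, params$relevance.b1, "+")
  a_relu <- a_pre > 0
  a <- a_pre; a[!a_relu] <- 0
  a_mask <- if (train) dropout_mask(dim(a), config$dense_dropout) else NULL
  a_d <- if (is.null(a_mask)) a else a * a_mask
  b_pre <- sweep(a_d %*% params$relevance.W2, 2L, params$relevance.b2, "+")
  b_relu <- b_pre > 0
  bb <- b_pre; bb[!b_relu] <- 0
  b_mask <- if (train) dropout_mask(dim(bb), config$dense_dropout) else NULL
  b_d <- if (is.null(b_mask)) bb else bb * b_mask
  th_pre <- sweep(b_d %*% params$relevance.W3, 2L, params$relevance.b3, "+")
  ln_t <- layernorm_forward(th_pre, params$relevance.ln.gamma,
                            params$relevance.ln.beta, config$layernorm_eps)
  theta <- ln_t$y

  # aggregation and head
  z <- rowSums(h_tilde * theta)
  p_pre <- outer(z, drop(params$head.W4)) +
    matrix(params$head.b4, B, config$head_units, byrow = TRUE)
  p_relu <- p_pre > 0
  p <- p_pre; p[!p_relu] <- 0
  p_mask <- if (train) dropout_mask(dim(p), config$dense_dropout) else NULL
  p_d <- if (is.null(p_mask)) p else p * p_mask
  logit <- drop(p_d %*% params$head.W5) + params$head.b5
  y_hat <- sigmoid(logit)
  if (any(!is.finite(y_hat))) {
    stop("non-finite activations in the classification head", call. = FALSE)
  }

  out <- list(x_gap = x_gap, h = h, h_tilde = h_tilde, theta = theta,
              z = z, y_hat = y_hat, state = state)
  if (keep_cache) {
    out$cache <- c(cache, list(
      gap = gap, gap_mask = gap_mask, Tp = Tp, B = B, feat = feat,
      h = h, ln_h = ln_h$cache, x_gap = x_gap,
      a_relu = a_relu, a_mask = a_mask, a_d = a_d,
      b_relu = b_relu, b_mask = b_mask, b_d = b_d,
      ln_t = ln_t$cache,
      h_tilde = h_tilde, theta = theta, z = z,
      p_relu = p_relu, p_mask = p_mask, p_d = p_d, y_hat = y_hat))
  }
  out
}

#' Concept diversity penalty
#'
#' Frobenius distance between the normalised Gram matrix of the concept
#' activation matrix and the identity:
#' `lambda * || G / (||G||_F + 1e-12) - I_K ||_F^2` with `G = H' H`. Drives
#' concepts toward mutual orthogonality. Over equal-norm orthogonal designs
#' the penalty equals `lambda * (sqrt(K) - 1)^2`.
#'
#' @param H B x K matrix of (post-layer-norm) concept activations.
#' @param lambda Penalty coefficient.
#' @return Scalar penalty value.
#' @export
diversity_penalty <- function(H, lambda = 1) {
  K <- ncol(H)
  G <- crossprod(H)
  s <- sqrt(sum(G * G))
  D <- G / (s + 1e-12) - diag(K)
  lambda * sum(D * D)
}

# gradient of diversity_penalty wrt H
diversity_penalty_grad <- function(H, lambda = 1) {
  K <- ncol(H)
  G <- crossprod(H)
  s <- sqrt(sum(G * G))
  u <- 1 / (s + 1e-12)
  D <- G * u - diag(K)
  dG <- 2 * lambda * (u * D - u^2 * sum(D * G) * (G / max(s, 1e-12)))
  2 * H %*% dG
}

#' Relevance sparsity penalty
#'
#' Mean L1 norm of the relevance rows, scaled by `lambda`: encourages each
#' prediction to rely on few concepts.
#'
#' @param Theta B x K relevance matrix.
#' @param lambda Penalty coefficient.
#' @return Scalar penalty value.
#' @export
sparsity_penalty <- function(Theta, lambda = 1) {
  lambda * sum(abs(Theta)) / nrow(Theta)
}

#' Relevance stability penalty
#'
#' Mean (over concepts) population variance of each relevance score across the
#' batch, scaled by `lambda`: similar inputs should receive similar
#' explanations. Returns 0 for a single-row batch.
#'
#' @param Theta B x K relevance matrix.
#' @param lambda Penalty coefficient.
#' @return Scalar penalty value.
#' @export
stability_penalty <- function(Theta, lambda = 1) {
  B <- nrow(Theta)
  if (B < 2L) return(0)
  mu <- colMeans(Theta)
  v <- colMeans(sweep(Theta, 2L, mu, "-")^2)
  lambda * mean(v)
}

#' Label-smoothed binary cross-entropy
#'
#' Standard smoothed BCE with target `y_s = y * (1 - eps) + eps / 2`,
#' probabilities clipped to `[1e-7, 1 - 1e-7]`, averaged with (normalised)
#' sample weights.
#'
#' @param y Binary labels (0/1).
#' @param y_hat Predicted probabilities in `[0, 1]`.
#' @param epsilon Smoothing factor.
#' @param weights Optional nonnegative sample weights (any scale; they are
#'   normalised internally, so rescaling them leaves the loss unchanged).
#' @return Scalar loss.
#' @export
smoothed_bce <- function(y, y_hat, epsilon = 0.05, weights = NULL) {
  if (any(y_hat < 0 | y_hat > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  p <- pmin(pmax(y_hat, 1e-7), 1 - 1e-7)
  ys <- y * (1 - epsilon) + epsilon / 2
  ll <- -(ys * log(p) + (1 - ys) * log(1 - p))
  if (is.null(weights)) mean(ll) else sum(weights * ll) / sum(weights)
}

#' Total SENN training loss
#'
#' Additive decomposition `total = bce + div + spar + stab (+ l2)` of the
#' training objective: weighted label-smoothed BCE, diversity penalty on the
#' post-layer-norm concept matrix, sparsity and stability penalties on the
#' relevance matrix, and the L2 penalty on convolutional kernels.
#'
#' @param outputs A [senn_forward()] result for the batch.
#' @param y Binary labels.
#' @param config A [senn_config()].
#' @param weights Optional sample weights for the BCE term.
#' @param params Optional parameter list; when supplied, the convolutional L2
#'   term is included as component `l2`.
#' @return Tibble with one row: columns `bce`, `div`, `spar`, `stab`, `l2`,
#'   `total`.
#' @export
total_loss <- function(outputs, y, config, weights = NULL, params = NULL) {
  bce <- smoothed_bce(y, outputs$y_hat, config$label_smoothing, weights)
  div <- diversity_penalty(outputs$h_tilde, config$lambda_div)
  spar <- sparsity_penalty(outputs$theta, config$lambda_spar)
  stab <- stability_penalty(outputs$theta, config$lambda_stab)
  l2 <- 0
  if (!is.null(params) && config$l2 > 0) {
    kn <- grep("conv[12]\\.W$|proj\\.W$", names(params), value = TRUE)
    l2 <- config$l2 * sum(vapply(params[kn], function(w) sum(w * w), 0))
  }
  tibble::tibble(bce = bce, div = div, spar = spar, stab = stab, l2 = l2,
                 total = bce + div + spar + stab + l2)
}
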