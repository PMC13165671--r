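# Backpropagation through the SENN and the AdamW update rule.
#
# Gradients are derived by hand, layer by layer, and validated against central
# finite differences in the test suite (tolerance ~1e-6 relative), which
# exercises every parameter of a small configuration.

#' Loss and parameter gradients for one batch
#'
#' Runs a training-mode forward pass (consuming the R random stream for
#' dropout / stochastic depth), evaluates the total loss and backpropagates it
#' to every trainable parameter.
#'
#' @param params,state Model parameters and batch-norm state.
#' @param x Batch array `B x T x C` (or time-major with `time_major = TRUE`).
#' @param y Binary labels (length B).
#' @param config A [senn_config()].
#' @param weights Optional per-sample BCE weights.
#' @param train Use training mode (dropout, stochastic depth, batch stats).
#' @param time_major Set if `x` is time-major `T x B x C`.
#' @return List with `loss` (one-row tibble), `grads` (named like `params`),
#'   `state` (updated running statistics) and `outputs`.
#' @export
senn_backward <- function(params, state, x, y, config, weights = NULL,
                          train = TRUE, time_major = FALSE) {
  fwd <- senn_forward(params, state, x, config, train = train,
                      keep_cache = TRUE, time_major = time_major)
  cc <- fwd$cache
  B <- cc$B
  loss <- total_loss(fwd, y, config, weights = weights, params = params)

  grads <- lapply(params, function(p) array(0, dim(p) %||% length(p)))
  names(grads) <- names(params)
  # keep vector parameters as plain vectors
  for (nm in names(params)) {
    if (is.null(dim(params[[nm]]))) grads[[nm]] <- numeric(length(params[[nm]]))
  }

  # ---- BCE head ----
  p <- pmin(pmax(fwd$y_hat, 1e-7), 1 - 1e-7)
  ys <- y * (1 - config$label_smoothing) + config$label_smoothing / 2
  w <- if (is.null(weights)) rep(1 / B, B) else weights / sum(weights)
  # d bce / d logit, exact where y_hat is inside the clipping interval
  inside <- fwd$y_hat > 1e-7 & fwd$y_hat < 1 - 1e-7
  dlogit <- w * (p - ys) * as.numeric(inside)

  grads[["head.b5"]] <- sum(dlogit)
  grads[["head.W5"]] <- crossprod(cc$p_d, dlogit)
  dp_d <- outer(dlogit, drop(params$head.W5))
  if (!is.null(cc$p_mask)) dp_d <- dp_d * cc$p_mask
  dp_pre <- dp_d * cc$p_relu
  grads[["head.b4"]] <- colSums(dp_pre)
  grads[["head.W4"]] <- matrix(colSums(dp_pre * fwd$z), 1L)
  dz <- drop(dp_pre %*% t(params$head.W4))

  # ---- aggregation and penalties ----
  dh_tilde <- cc$theta * dz
  dtheta <- cc$h_tilde * dz
  if (config$lambda_div > 0) {
    dh_tilde <- dh_tilde + diversity_penalty_grad(cc$h_tilde, config$lambda_div)
  }
  if (config$lambda_spar > 0) {
    dtheta <- dtheta + config$lambda_spar * sign(cc$theta) / B
  }
  if (config$lambda_stab > 0 && B >= 2L) {
    K <- ncol(cc$theta)
    centred <- sweep(cc$theta, 2L, colMeans(cc$theta), "-")
    dtheta <- dtheta + config$lambda_stab * 2 * centred / (B * K)
  }

  # ---- relevance branch ----
  ln_t <- layernorm_backward(dtheta, params$relevance.ln.gamma, cc$ln_t)
  grads[["relevance.ln.gamma"]] <- ln_t$dgamma
  grads[["relevance.ln.beta"]] <- ln_t$dbeta
  dth_pre <- ln_t$dx
  grads[["relevance.W3"]] <- crossprod(cc$b_d, dth_pre)
  grads[["relevance.b3"]] <- colSums(dth_pre)
  db_d <- dth_pre %*% t(params$relevance.W3)
  if (!is.null(cc$b_mask)) db_d <- db_d * cc$b_mask
  db_pre <- db_d * cc$b_relu
  grads[["relevance.W2"]] <- crossprod(cc$a_d, db_pre)
  grads[["relevance.b2"]] <- colSums(db_pre)
  da_d <- db_pre %*% t(params$relevance.W2)
  if (!is.null(cc$a_mask)) da_d <- da_d * cc$a_mask
  da_pre <- da_d * cc$a_relu
  grads[["relevance.W1"]] <- crossprod(cc$x_gap, da_pre)
  grads[["relevance.b1"]] <- colSums(da_pre)
  dxgap <- da_pre %*% t(params$relevance.W1)

  # ---- concept branch ----
  ln_h <- layernorm_backward(dh_tilde, params$concept.ln.gamma, cc$ln_h)
  grads[["concept.ln.gamma"]] <- ln_h$dgamma
  grads[["concept.ln.beta"]] <- ln_h$dbeta
  dh_pre <- ln_h$dx * (1 - cc$h^2)
  grads[["concept.W"]] <- crossprod(cc$x_gap, dh_pre)
  grads[["concept.b"]] <- colSums(dh_pre)
  dxgap <- dxgap + dh_pre %*% t(params$concept.W)

  # ---- pooling ----
  if (!is.null(cc$gap_mask)) dxgap <- dxgap * cc$gap_mask
  Tp <- cc$Tp
  dcur <- array(rep(as.vector(dxgap) / Tp, each = Tp), c(Tp, B, cc$feat))

  # ---- residual blocks, deepest first ----
  dy <- dcur
  for (i in 4:1) {
    pfx <- paste0("block", i, ".")
    bc <- fwd$cache$blocks[[i]]
    if (i < 4L) dy <- maxpool2_backward(dy, bc$pool)
    Tn <- dim(dy)[1L]
    has_proj <- !is.null(params[[paste0(pfx, "proj.W")]])
    proj_X2 <- NULL
    if (has_proj && !is.null(bc$x_in)) {
      proj_X2 <- bc$x_in                        # k = 1: im2col is a reshape
      dim(proj_X2) <- c(Tn * B, dim(bc$x_in)[3L])
    }
    if (isTRUE(bc$dropped)) {
      if (has_proj) {
        cb <- conv1d_backward(dy, proj_X2, params[[paste0(pfx, "proj.W")]],
                              Tn, B)
        grads[[paste0(pfx, "proj.W")]] <- cb$dW
        grads[[paste0(pfx, "proj.b")]] <- cb$db
        dy <- cb$dx
      }
      next
    }
    dpre <- dy * bc$relu_out
    dskip <- dpre
    bn2 <- batchnorm_backward(dpre, params[[paste0(pfx, "bn2.gamma")]], bc$bn2)
    grads[[paste0(pfx, "bn2.gamma")]] <- bn2$dgamma
    grads[[paste0(pfx, "bn2.beta")]] <- bn2$dbeta
    cb2 <- conv1d_backward(bn2$dx, bc$X2_2, params[[paste0(pfx, "conv2.W")]],
                           Tn, B)
    grads[[paste0(pfx, "conv2.W")]] <- cb2$dW
    grads[[paste0(pfx, "conv2.b")]] <- cb2$db
    da1d <- cb2$dx
    if (!is.null(bc$sd_mask)) da1d <- da1d * bc$sd_mask
    da1 <- da1d * bc$relu1
    bn1 <- batchnorm_backward(da1, params[[paste0(pfx, "bn1.gamma")]], bc$bn1)
    grads[[paste0(pfx, "bn1.gamma")]] <- bn1$dgamma
    grads[[paste0(pfx, "bn1.beta")]] <- bn1$dbeta
    cb1 <- conv1d_backward(bn1$dx, bc$X2_1, params[[paste0(pfx, "conv1.W")]],
                           Tn, B)
    grads[[paste0(pfx, "conv1.W")]] <- cb1$dW
    grads[[paste0(pfx, "conv1.b")]] <- cb1$db
    dx <- cb1$dx
    if (has_proj) {
      cbp <- conv1d_backward(dskip, proj_X2, params[[paste0(pfx, "proj.W")]],
                             Tn, B)
      grads[[paste0(pfx, "proj.W")]] <- cbp$dW
      grads[[paste0(pfx, "proj.b")]] <- cbp$db
      dx <- dx + cbp$dx
    } else {
      dx <- dx + dskip
    }
    dy <- dx
  }

  # ---- convolutional L2 (loss term; decoupled weight decay is separate) ----
  if (config$l2 > 0) {
    for (nm in grep("conv[12]\\.W$|proj\\.W$", names(params), value = TRUE)) {
      grads[[nm]] <- grads[[nm]] + 2 * config$l2 * params[[nm]]
    }
  }

  list(loss = loss, grads = grads, state = fwd$state,
       outputs = fwd[c("x_gap", "h", "h_tilde", "theta", "z", "y_hat")])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
adamw_init <- function(params) {
  list(t = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

# One AdamW step: bias-corrected Adam moments plus decoupled weight decay on
# weight matrices and convolution kernels (biases and normalisation affines
# are not decayed).
#' @noRd
adamw_step <- function(opt, params, grads, lr, weight_decay = 0,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  decay_set <- grepl("\\.W[0-9]?$", names(params))
  for (i in seq_along(params)) {
    g <- grads[[i]]
    opt$m[[i]] <- beta1 * opt$m[[i]] + (1 - beta1) * g
    opt$v[[i]] <- beta2 * opt$v[[i]] + (1 - beta2) * g * g
    mhat <- opt$m[[i]] / bc1
    vhat <- opt$v[[i]] / bc2
    step <- mhat / (sqrt(vhat) + eps)
    if (weight_decay > 0 && decay_set[i]) step <- step + weight_decay * params[[i]]
    params[[i]] <- params[[i]] - lr * step
  }
  list(opt = opt, params = params)
}
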