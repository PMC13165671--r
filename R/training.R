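# Class weighting, optimiser schedule, smoothed early stopping, single-seed
# training and multi-seed summarisation.

#' Optimiser and schedule specification
#'
#' AdamW with decoupled weight decay, linear warm-up followed by cosine
#' annealing, batch size 64, and smoothed early stopping on the validation
#' AUC. `t_max` is both the cosine horizon and the maximum epoch count.
#'
#' @param alpha0 Peak learning rate reached at the end of warm-up.
#' @param alpha_min Learning-rate floor reached at `t_max`.
#' @param warmup Warm-up epochs.
#' @param t_max Maximum epochs / cosine horizon.
#' @param weight_decay Decoupled AdamW weight decay.
#' @param batch_size Windows per gradient step.
#' @param patience Early-stopping patience (epochs without smoothed-AUC
#'   improvement).
#' @param smooth_window Rolling-mean window of the early-stopping criterion.
#' @return An `optimizer_spec` list.
#' @export
optimizer_spec <- function(alpha0 = 5e-4, alpha_min = 1e-6, warmup = 5L,
                           t_max = 120L, weight_decay = 2e-4,
                           batch_size = 64L, patience = 12L,
                           smooth_window = 3L) {
  stopifnot(warmup >= 0L, warmup < t_max, alpha_min < alpha0,
            batch_size >= 1L, patience >= 1L, smooth_window >= 1L)
  structure(list(alpha0 = alpha0, alpha_min = alpha_min,
                 warmup = as.integer(warmup), t_max = as.integer(t_max),
                 weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 smooth_window = as.integer(smooth_window)),
            class = "optimizer_spec")
}

#' Balanced class weights
#'
#' `w_c = N / (C * N_c)` from per-class training-window counts, so that
#' `sum_c N_c * w_c = N` exactly.
#'
#' @param window_counts Counts per class; named vector (names "0"/"1") or
#'   unnamed length-2 vector ordered (class 0, class 1).
#' @return List with `w` (named per-class weights), `counts`, `N`.
#' @export
class_weights <- function(window_counts) {
  if (is.null(names(window_counts))) {
    names(window_counts) <- as.character(seq_along(window_counts) - 1L)
  }
  if (any(window_counts < 1L)) {
    stop("degenerate training set: a class has no windows", call. = FALSE)
  }
  N <- sum(window_counts)
  C <- length(window_counts)
  w <- N / (C * window_counts)
  list(w = w, counts = window_counts, N = N)
}

#' Warm-up + cosine learning-rate schedule
#'
#' `t < warmup`: linear ramp `alpha0 * t / warmup`; afterwards cosine decay
#' from `alpha0` (at `t = warmup`) to `alpha_min` (at `t = t_max`).
#'
#' @param t Epoch in `[0, t_max]` (fractional values allowed).
#' @param spec An [optimizer_spec()].
#' @return Learning rate.
#' @export
learning_rate <- function(t, spec) {
  stopifnot(inherits(spec, "optimizer_spec"))
  if (any(t < 0 | t > spec$t_max)) {
    stop(sprintf("epoch t must lie in [0, %d]", spec$t_max), call. = FALSE)
  }
  ifelse(t < spec$warmup,
         spec$alpha0 * t / spec$warmup,
         spec$alpha_min + 0.5 * (spec$alpha0 - spec$alpha_min) *
           (1 + cos((t - spec$warmup) * pi / (spec$t_max - spec$warmup))))
}

#' Initialise smoothed early stopping
#' @param smooth_window Rolling-mean window (epochs).
#' @param patience Non-improving epochs tolerated.
#' @return An `early_stop_state`.
#' @export
early_stop_state <- function(smooth_window = 3L, patience = 12L) {
  structure(list(auc_history = numeric(0), smooth_window = as.integer(smooth_window),
                 patience = as.integer(patience), best_smoothed = -Inf,
                 epochs_since_best = 0L, best_epoch = NA_integer_,
                 continue = TRUE, improved = FALSE),
            class = "early_stop_state")
}

#' Update smoothed early stopping with one epoch's validation AUC
#'
#' Tracks the rolling mean of the validation AUC over the last
#' `smooth_window` epochs (partial means before the window fills).
#' Improvement requires the smoothed value to exceed the best by more than
#' 1e-6; after `patience` consecutive non-improving epochs `continue` turns
#' `FALSE` and the caller restores the checkpoint of `best_epoch`.
#'
#' @param state An `early_stop_state`.
#' @param epoch_auc Validation AUC of the finished epoch.
#' @return Updated state with fields `continue`, `improved`, `best_epoch`,
#'   `best_smoothed`, `epochs_since_best`.
#' @export
early_stop_update <- function(state, epoch_auc) {
  stopifnot(inherits(state, "early_stop_state"))
  state$auc_history <- c(state$auc_history, epoch_auc)
  n <- length(state$auc_history)
  w <- min(state$smooth_window, n)
  smoothed <- mean(state$auc_history[(n - w + 1L):n])
  if (smoothed > state$best_smoothed + 1e-6) {
    state$best_smoothed <- smoothed
    state$best_epoch <- n
    state$epochs_since_best <- 0L
    state$improved <- TRUE
  } else {
    state$epochs_since_best <- state$epochs_since_best + 1L
    state$improved <- FALSE
  }
  state$continue <- state$epochs_since_best < state$patience
  state
}

# batched deterministic (eval-mode) forward pass over a window array
#' Evaluate the SENN on windows
#' @param model A `senn_model` (or list with params/state/config).
#' @param windows B x L x C array or a `window_batch`.
#' @param chunk Mini-batch size of the evaluation pass.
#' @return List of matrices/vectors `y_hat`, `z`, `h`, `h_tilde`, `theta`,
#'   `x_gap`.
#' @export
senn_evaluate <- function(model, windows, chunk = 256L) {
  if (inherits(windows, "window_batch")) windows <- windows$windows
  B <- dim(windows)[1L]
  K <- model$config$K
  feat <- model$config$filters[4L]
  out <- list(y_hat = numeric(B), z = numeric(B),
              h = matrix(0, B, K), h_tilde = matrix(0, B, K),
              theta = matrix(0, B, K), x_gap = matrix(0, B, feat))
  at <- 1L
  while (at <= B) {
    hi <- min(B, at + chunk - 1L)
    fw <- senn_forward(model$params, model$state,
                       windows[at:hi, , , drop = FALSE], model$config,
                       train = FALSE)
    out$y_hat[at:hi] <- fw$y_hat
    out$z[at:hi] <- fw$z
    out$h[at:hi, ] <- fw$h
    out$h_tilde[at:hi, ] <- fw$h_tilde
    out$theta[at:hi, ] <- fw$theta
    out$x_gap[at:hi, ] <- fw$x_gap
    at <- hi + 1L
  }
  out
}

#' Train the SENN on one seed
#'
#' Minimises the total loss (weighted label-smoothed BCE plus diversity,
#' sparsity, stability and convolutional L2 penalties) with AdamW under the
#' warm-up/cosine schedule, monitors the window-level validation AUC with
#' smoothed early stopping, and restores the parameters of the best smoothed
#' epoch. The seed drives initialisation, shuffling, dropout, stochastic
#' depth — everything stochastic in the fit.
#'
#' @param train,val `window_batch`es of the train and validation partitions.
#' @param config A [senn_config()].
#' @param optimizer An [optimizer_spec()].
#' @param seed Integer seed.
#' @param verbose Print one line per epoch.
#' @return A `senn_model`: trained `params`/`state`, `config`, `history`
#'   tibble (epoch, lr, loss components, accuracies, validation AUCs),
#'   `best_epoch`, `class_weights`, `seed`.
#' @export
train_senn <- function(train, val, config = senn_config(),
                       optimizer = optimizer_spec(), seed = 42L,
                       verbose = FALSE) {
  stopifnot(inherits(train, "window_batch"), inherits(val, "window_batch"))
  assert_disjoint_subjects(train, val)
  set.seed(seed)
  ini <- senn_init(config)
  params <- ini$params
  state <- ini$state
  opt <- adamw_init(params)
  cw <- class_weights(c("0" = sum(train$labels == 0L),
                        "1" = sum(train$labels == 1L)))
  sw <- unname(cw$w[as.character(train$labels)])
  es <- early_stop_state(optimizer$smooth_window, optimizer$patience)
  B <- length(train)
  hist <- vector("list", optimizer$t_max)
  best <- list(params = params, state = state)
  for (epoch in seq_len(optimizer$t_max)) {
    lr <- learning_rate(epoch, optimizer)
    idx <- sample.int(B)
    nb <- ceiling(B / optimizer$batch_size)
    ep_loss <- c(bce = 0, div = 0, spar = 0, stab = 0, l2 = 0, total = 0)
    ep_correct <- 0
    for (bi in seq_len(nb)) {
      sel <- idx[((bi - 1L) * optimizer$batch_size + 1L):min(bi * optimizer$batch_size, B)]
      xb <- train$windows[sel, , , drop = FALSE]
      yb <- train$labels[sel]
      bk <- senn_backward(params, state, xb, yb, config, weights = sw[sel],
                          train = TRUE)
      if (!is.finite(bk$loss$total)) {
        bad <- names(bk$loss)[!vapply(bk$loss, is.finite, TRUE)]
        stop(sprintf("NaN loss at epoch %d (component: %s)", epoch,
                     paste(bad, collapse = ",")), call. = FALSE)
      }
      state <- bk$state
      st <- adamw_step(opt, params, bk$grads, lr, optimizer$weight_decay)
      opt <- st$opt
      params <- st$params
      ep_loss <- ep_loss + unlist(bk$loss[1L, ]) * length(sel)
      ep_correct <- ep_correct + sum((bk$outputs$y_hat > 0.5) == (yb == 1L))
    }
    ep_loss <- ep_loss / B
    model_now <- list(params = params, state = state, config = config)
    ev <- senn_evaluate(model_now, val)
    val_auc <- roc_auc(val$labels, ev$y_hat)
    val_acc <- mean((ev$y_hat > 0.5) == (val$labels == 1L))
    sp <- pool_subject_probabilities(ev$y_hat, val$subject_ids)
    vl <- val$labels[!duplicated(val$subject_ids)]
    names(vl) <- val$subject_ids[!duplicated(val$subject_ids)]
    val_auc_subj <- roc_auc(vl[names(sp)], sp)
    es <- early_stop_update(es, val_auc)
    if (es$improved) best <- list(params = params, state = state)
    hist[[epoch]] <- tibble::tibble(
      epoch = epoch, lr = lr, bce = ep_loss["bce"], div = ep_loss["div"],
      spar = ep_loss["spar"], stab = ep_loss["stab"], l2 = ep_loss["l2"],
      loss = ep_loss["total"], train_acc = ep_correct / B,
      val_acc = val_acc, val_auc = val_auc, val_auc_subject = val_auc_subj,
      smoothed_auc = mean(utils::tail(es$auc_history, es$smooth_window)))
    if (verbose) {
      message(sprintf("epoch %3d lr %.2e loss %.4f val_auc %.4f%s", epoch, lr,
                      ep_loss["total"], val_auc,
                      if (es$improved) " *" else ""))
    }
    if (!es$continue) break
  }
  structure(list(params = best$params, state = best$state, config = config,
                 optimizer = optimizer,
                 history = dplyr::bind_rows(hist[!vapply(hist, is.null, TRUE)]),
                 best_epoch = es$best_epoch, class_weights = cw, seed = seed),
            class = "senn_model")
}

#' @export
print.senn_model <- function(x, ...) {
  cat(sprintf("<senn_model> K=%d concepts, %d epochs trained (best %d), seed %d\n",
              x$config$K, nrow(x$history), x$best_epoch, x$seed))
  invisible(x)
}

#' @export
predict.senn_model <- function(object, newdata, ...) {
  ev <- senn_evaluate(object, newdata)
  tibble::tibble(y_hat = ev$y_hat, z = ev$z)
}

#' Multi-seed summary with t-distribution confidence interval
#'
#' Mean, sample standard deviation and the 95% interval
#' `mean +/- t(0.975, n-1) * s / sqrt(n)` of a per-seed metric vector (for
#' the study's five seeds the critical value is 2.776).
#'
#' @param values Numeric vector of per-seed metric values (n >= 2), or a
#'   tibble of per-seed metric columns to summarise column-wise (a `metric`
#'   column per row is returned).
#' @param conf Confidence level.
#' @return Tibble with columns `metric` (when summarising a tibble), `mean`,
#'   `sd`, `n`, `ci_low`, `ci_high`, `t_crit`.
#' @export
summarise_seeds <- function(values, conf = 0.95) {
  if (is.data.frame(values)) {
    num <- values[vapply(values, is.numeric, TRUE)]
    num <- num[setdiff(names(num), "seed")]
    return(dplyr::bind_rows(lapply(names(num), function(nm) {
      dplyr::mutate(summarise_seeds(num[[nm]], conf), metric = nm,
                    .before = 1L)
    })))
  }
  n <- length(values)
  if (n < 2L) stop("need at least two seeds to summarise", call. = FALSE)
  m <- mean(values)
  s <- stats::sd(values)
  tc <- stats::qt(1 - (1 - conf) / 2, df = n - 1L)
  half <- tc * s / sqrt(n)
  tibble::tibble(mean = m, sd = s, n = n, ci_low = m - half,
                 ci_high = m + half, t_crit = tc)
}
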