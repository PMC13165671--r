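# Temperature scaling, subject pooling, macro-F1 threshold selection and the
# metric suite.

clip01 <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

logit <- function(p) log(p / (1 - p))

#' Apply a temperature to probabilities
#'
#' `sigma(logit(p) / T)`: a strictly monotone transform, so rankings (and
#' therefore ROC-AUC) are preserved for any `T > 0`.
#'
#' @param probs Probabilities in (0, 1) (clipped internally).
#' @param temperature Positive scalar `T`.
#' @return Calibrated probabilities.
#' @export
apply_temperature <- function(probs, temperature) {
  stopifnot(temperature > 0)
  if (temperature == 1) return(probs)
  sigmoid(logit(clip01(probs)) / temperature)
}

nll_at_temperature <- function(Tv, lg, y) {
  p <- clip01(sigmoid(lg / Tv))
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Fit a temperature scaler on validation probabilities
#'
#' Minimises the negative log-likelihood of the logit-scaled probabilities
#' over `T` in `[0.25, 10]`: a log-spaced coarse grid followed by local
#' refinement to `|dT| < 1e-4`. The fitted temperature never increases the
#' fitting-set NLL relative to `T = 1`.
#'
#' @param probs Validation window probabilities.
#' @param labels Binary labels (both classes required).
#' @return A `temperature_scaler` with fields `T`, `fit_nll`, `nll_at_unit`.
#' @export
fit_temperature <- function(probs, labels) {
  if (length(unique(labels)) < 2L) {
    stop("temperature fitting requires both classes", call. = FALSE)
  }
  lg <- logit(clip01(probs))
  grid <- exp(seq(log(0.25), log(10), length.out = 41L))
  nlls <- vapply(grid, nll_at_temperature, 0, lg = lg, y = labels)
  i <- which.min(nlls)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  op <- stats::optimize(nll_at_temperature, c(lo, hi), lg = lg, y = labels,
                        tol = 1e-5)
  Tv <- op$minimum
  fit_nll <- op$objective
  unit <- nll_at_temperature(1, lg, labels)
  if (fit_nll > unit) {
    Tv <- 1
    fit_nll <- unit
  }
  structure(list(T = Tv, fit_nll = fit_nll, nll_at_unit = unit),
            class = "temperature_scaler")
}

#' @export
print.temperature_scaler <- function(x, ...) {
  cat(sprintf("<temperature_scaler> T = %.4f (NLL %.4f vs %.4f at T=1)\n",
              x$T, x$fit_nll, x$nll_at_unit))
  invisible(x)
}

#' Pool window probabilities to subjects
#'
#' The subject probability is the arithmetic mean of that subject's
#' (calibrated) window probabilities.
#'
#' @param window_probs Per-window probabilities.
#' @param subject_ids Per-window subject identifiers.
#' @return Named numeric vector of per-subject probabilities (in order of
#'   first appearance).
#' @export
pool_subject_probabilities <- function(window_probs, subject_ids) {
  stopifnot(length(window_probs) == length(subject_ids))
  f <- factor(subject_ids, levels = unique(subject_ids))
  m <- tapply(window_probs, f, mean)[levels(f)]
  stats::setNames(as.numeric(m), levels(f))
}

macro_f1_at <- function(probs, labels, tau) {
  pred <- as.integer(probs >= tau)
  f1 <- function(pos) {
    tp <- sum(pred == pos & labels == pos)
    fp <- sum(pred == pos & labels != pos)
    fn <- sum(pred != pos & labels == pos)
    den <- 2 * tp + fp + fn
    if (den == 0) 0 else 2 * tp / den
  }
  (f1(1L) + f1(0L)) / 2
}

#' Select the decision threshold by macro-averaged F1
#'
#' Scans the grid `{step, 2*step, ..., 1 - step}` of thresholds on the
#' (subject-level) probabilities and returns the threshold maximising the
#' macro-averaged F1 across both classes; ties are broken toward the largest
#' threshold (favouring specificity).
#'
#' @param subject_probs Per-subject probabilities.
#' @param labels Per-subject binary labels.
#' @param step Grid step (default 0.01).
#' @return List (`operating_point`) with `tau` and `macro_f1`.
#' @export
select_threshold <- function(subject_probs, labels, step = 0.01) {
  if (length(unique(labels)) < 2L) {
    stop("threshold selection requires both classes", call. = FALSE)
  }
  grid <- seq(step, 1 - step, by = step)
  f1s <- vapply(grid, macro_f1_at, 0, probs = subject_probs, labels = labels)
  best <- max(f1s)
  tau <- grid[max(which(f1s >= best - 1e-12))]
  structure(list(tau = tau, macro_f1 = best), class = "operating_point")
}

#' Threshold-dependent classification metrics from a confusion matrix
#'
#' @param tp,fn,fp,tn Confusion counts (PD is the positive class).
#' @return One-row tibble: `sensitivity`, `specificity`, `accuracy`, `f1_pd`,
#'   `macro_f1`, plus the counts. Ratios with zero denominators are reported
#'   as 0.
#' @export
classification_metrics <- function(tp, fn, fp, tn) {
  total <- tp + fn + fp + tn
  if (total < 1L) stop("empty confusion matrix", call. = FALSE)
  safe <- function(num, den) if (den == 0) 0 else num / den
  sens <- safe(tp, tp + fn)
  spec <- safe(tn, tn + fp)
  f1_pd <- safe(2 * tp, 2 * tp + fp + fn)
  f1_hc <- safe(2 * tn, 2 * tn + fn + fp)
  tibble::tibble(sensitivity = sens, specificity = spec,
                 accuracy = (tp + tn) / total, f1_pd = f1_pd,
                 macro_f1 = (f1_pd + f1_hc) / 2,
                 tp = tp, fn = fn, fp = fp, tn = tn)
}

#' Confusion counts at a threshold
#' @param probs Probabilities; `labels` binary; `tau` threshold.
#' @return Named vector `tp`, `fn`, `fp`, `tn`.
#' @export
confusion_at <- function(probs, labels, tau) {
  pred <- as.integer(probs >= tau)
  c(tp = sum(pred == 1L & labels == 1L), fn = sum(pred == 0L & labels == 1L),
    fp = sum(pred == 1L & labels == 0L), tn = sum(pred == 0L & labels == 0L))
}

#' ROC-AUC by the rank (Mann-Whitney) statistic
#'
#' Midranks give the standard tie correction; invariant under strictly
#' monotone transforms of the scores.
#'
#' @param labels Binary labels (both classes required).
#' @param probs Scores/probabilities.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(labels, probs) {
  pos <- labels == 1L
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("AUC requires both classes", call. = FALSE)
  r <- rank(probs)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Average precision (step-wise precision-recall integral)
#'
#' `AP = sum_n (R_n - R_{n-1}) * P_n` over descending score order.
#'
#' @param labels Binary labels; `probs` scores.
#' @return Average precision in `[0, 1]`.
#' @export
average_precision <- function(labels, probs) {
  if (length(unique(labels)) < 2L) stop("AP requires both classes",
                                        call. = FALSE)
  o <- order(probs, decreasing = TRUE)
  y <- labels[o]
  s <- probs[o]
  tp <- cumsum(y == 1L)
  fp <- cumsum(y == 0L)
  # evaluate at distinct thresholds only (ties grouped)
  last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / sum(labels == 1L)
  sum(diff(c(0, rec)) * prec)
}

#' Brier score
#' @param labels Binary labels; `probs` probabilities.
#' @return Mean squared error between probabilities and labels.
#' @export
brier_score <- function(labels, probs) mean((probs - labels)^2)

#' Expected calibration error
#'
#' Equal-width bins on the predicted positive-class probability;
#' `sum_b (n_b / n) * |mean(p_b) - frac_pos_b|`.
#'
#' @param labels Binary labels; `probs` probabilities.
#' @param bins Number of equal-width bins.
#' @return List with `ece` and the per-bin `table` (tibble).
#' @export
expected_calibration_error <- function(labels, probs, bins = 10L) {
  edges <- seq(0, 1, length.out = bins + 1L)
  b <- pmin(pmax(findInterval(probs, edges, rightmost.closed = TRUE), 1L),
            bins)
  tab <- tibble::tibble(bin = seq_len(bins),
                        lower = edges[-(bins + 1L)], upper = edges[-1L]) |>
    dplyr::left_join(
      tibble::tibble(bin = b, p = probs, y = labels) |>
        dplyr::group_by(.data$bin) |>
        dplyr::summarise(n = dplyr::n(), mean_prob = mean(.data$p),
                         frac_pos = mean(.data$y)),
      by = "bin") |>
    tidyr::replace_na(list(n = 0L))
  nz <- tab$n > 0L
  ece <- sum(tab$n[nz] / length(probs) *
               abs(tab$mean_prob[nz] - tab$frac_pos[nz]))
  list(ece = ece, table = tab)
}

#' Probabilistic metric suite
#'
#' ROC-AUC (rank statistic with tie correction), average precision, Brier
#' score and expected calibration error.
#'
#' @param labels Binary labels; `probs` probabilities.
#' @param ece_bins ECE bin count.
#' @return One-row tibble `roc_auc`, `avg_precision`, `brier`, `ece`.
#' @export
probabilistic_metrics <- function(labels, probs, ece_bins = 10L) {
  tibble::tibble(
    roc_auc = roc_auc(labels, probs),
    avg_precision = average_precision(labels, probs),
    brier = brier_score(labels, probs),
    ece = expected_calibration_error(labels, probs, ece_bins)$ece)
}
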