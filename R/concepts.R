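# Concept contribution statistics, class-gap / effect-size rankings, and
# concept x anatomical-sensor-group correlation.

#' Default anatomical sensor-group map
#'
#' Assigns each of the 16 channels to one of eight groups (left/right x
#' heel, midfoot, forefoot, toe) following the per-foot region layout of
#' [foot_region_map()]. Override for real insole layouts by supplying your
#' own character vector of length 16.
#'
#' @param per_foot Character vector of length 8 mapping each foot's channels
#'   to regions.
#' @return Character vector of length 16 with group names like
#'   `"left_heel"`.
#' @export
sensor_group_map <- function(per_foot = foot_region_map()) {
  stopifnot(length(per_foot) == 8L)
  g <- c(paste0("left_", per_foot), paste0("right_", per_foot))
  if (length(unique(g)) != 8L) {
    stop("the map must produce exactly 8 non-empty groups", call. = FALSE)
  }
  g
}

#' Concept contributions
#'
#' Element `(n, k)` is `h_tilde_k(X_n) * theta_k(X_n)`; each row sums to the
#' aggregate `z(X_n)` consumed by the classification head — the explanation
#' is the computation.
#'
#' @param outputs Eval-mode [senn_evaluate()] result (fields `h_tilde`,
#'   `theta`).
#' @return B x K matrix of contributions.
#' @export
contributions <- function(outputs) {
  outputs$h_tilde * outputs$theta
}

#' Class gap and effect size per concept
#'
#' For each concept: the absolute difference of mean contributions between
#' PD and healthy windows (`delta`), and the signed Cohen's d (PD minus HC)
#' using the pooled `(n-1)`-weighted standard deviation. Zero pooled spread
#' yields a signed infinite `d` (flagged).
#'
#' @param contrib B x K contribution matrix.
#' @param labels Per-window binary labels (both classes, each with >= 2
#'   windows for `d`).
#' @return Tibble with `concept`, `delta`, `cohens_d`, `mean_pd`, `mean_hc`,
#'   `zero_spread`.
#' @export
discriminative_stats <- function(contrib, labels) {
  if (length(unique(labels)) < 2L) {
    stop("both classes are required", call. = FALSE)
  }
  pd <- contrib[labels == 1L, , drop = FALSE]
  hc <- contrib[labels == 0L, , drop = FALSE]
  n1 <- nrow(pd); n0 <- nrow(hc)
  m1 <- colMeans(pd); m0 <- colMeans(hc)
  v1 <- apply(pd, 2L, stats::var)
  v0 <- apply(hc, 2L, stats::var)
  pooled <- sqrt(((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2))
  diff <- m1 - m0
  d <- ifelse(pooled > 0, diff / pooled, sign(diff) * Inf)
  tibble::tibble(concept = seq_len(ncol(contrib)), delta = abs(diff),
                 cohens_d = d, mean_pd = m1, mean_hc = m0,
                 zero_spread = pooled == 0)
}

#' Concept x sensor-group Pearson correlation
#'
#' For every window the group signal is the mean of the group's raw channels
#' over all timesteps; entry `(k, g)` is the Pearson correlation between
#' concept `k` activations and group `g` signals across windows.
#' Zero-variance columns give `r = 0` (flagged via attribute
#' `"zero_variance"`).
#'
#' @param h_matrix B x K concept activation matrix (post layer-norm).
#' @param raw_windows B x L x 16 array of raw (unstandardised) windows.
#' @param group_map Channel-to-group assignment from [sensor_group_map()].
#' @return K x 8 matrix of correlations (columns named by group).
#' @export
concept_sensor_correlation <- function(h_matrix, raw_windows,
                                       group_map = sensor_group_map()) {
  B <- nrow(h_matrix)
  stopifnot(B >= 3L, dim(raw_windows)[1L] == B,
            dim(raw_windows)[3L] == length(group_map))
  groups <- unique(group_map)
  # per-window mean over each group's channels and all timesteps
  gs <- vapply(groups, function(g) {
    ch <- which(group_map == g)
    x <- raw_windows[, , ch, drop = FALSE]
    rowMeans(matrix(x, nrow = B))
  }, numeric(B))
  zero_h <- apply(h_matrix, 2L, stats::sd) == 0
  zero_g <- apply(gs, 2L, stats::sd) == 0
  r <- matrix(0, ncol(h_matrix), length(groups),
              dimnames = list(NULL, groups))
  ok_h <- which(!zero_h)
  ok_g <- which(!zero_g)
  if (length(ok_h) > 0L && length(ok_g) > 0L) {
    r[ok_h, ok_g] <- stats::cor(h_matrix[, ok_h, drop = FALSE],
                                gs[, ok_g, drop = FALSE])
  }
  attr(r, "zero_variance") <- any(zero_h) || any(zero_g)
  r
}

#' Assemble the concept report
#'
#' Contributions, class gaps, effect sizes, sensor-group correlations, the
#' gap-descending concept ranking and per-window top-`m` explanations.
#'
#' @param outputs Eval-mode [senn_evaluate()] result.
#' @param labels Per-window binary labels.
#' @param raw_windows B x L x 16 array of raw windows (for correlations);
#'   `NULL` to skip.
#' @param group_map Channel-to-group assignment.
#' @param top_m Concepts listed per window in the explanation table.
#' @param subject_ids Optional per-window subject ids for the explanation
#'   table.
#' @return A `concept_report`: list with `contrib` (B x K), `stats` (tibble,
#'   ranked columns), `sensor_corr` (K x 8 or NULL), `ranking` (permutation
#'   of 1..K, delta descending, ties by concept index), `explanations`
#'   (tibble of per-window top contributions).
#' @export
concept_report <- function(outputs, labels, raw_windows = NULL,
                           group_map = sensor_group_map(), top_m = 5L,
                           subject_ids = NULL) {
  cm <- contributions(outputs)
  # row sums must reproduce z: the structural identity of the architecture
  stopifnot(all(abs(rowSums(cm) - outputs$z) <= 1e-6 * (1 + abs(outputs$z))))
  stats <- discriminative_stats(cm, labels)
  ranking <- order(-stats$delta, stats$concept)
  sc <- if (!is.null(raw_windows)) {
    concept_sensor_correlation(outputs$h_tilde, raw_windows, group_map)
  } else NULL
  if (!is.null(sc)) {
    stats$top_group <- colnames(sc)[apply(abs(sc), 1L, which.max)]
    stats$top_group_r <- sc[cbind(seq_len(nrow(sc)),
                                  apply(abs(sc), 1L, which.max))]
  }
  B <- nrow(cm)
  m <- min(top_m, ncol(cm))
  expl <- purrr::map_dfr(seq_len(B), function(n) {
    ord <- order(-abs(cm[n, ]))[seq_len(m)]
    tibble::tibble(window = n,
                   subject_id = if (is.null(subject_ids)) NA_character_
                   else subject_ids[n],
                   label = labels[n], rank = seq_len(m), concept = ord,
                   contribution = cm[n, ord])
  })
  structure(list(contrib = cm, stats = stats, sensor_corr = sc,
                 ranking = ranking, explanations = expl),
            class = "concept_report")
}

#' @export
print.concept_report <- function(x, ...) {
  top <- x$ranking[1L]
  cat(sprintf("<concept_report> %d windows x %d concepts; top concept %d (delta %.3f, d %.2f)\n",
              nrow(x$contrib), ncol(x$contrib), top,
              x$stats$delta[top], x$stats$cohens_d[top]))
  invisible(x)
}
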