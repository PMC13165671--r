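# Training-set-only three-stage window augmentation:
# Gaussian jitter -> random channel dropout -> same-class CutMix.

#' Augmentation configuration
#'
#' @param noise_sd Additive Gaussian noise standard deviation (z-score
#'   units).
#' @param channel_drop_range Integer set of possible dropped-channel counts.
#' @param cutmix_len_range Inclusive range of CutMix segment lengths in
#'   timesteps.
#' @param copies Augmented copies generated per original window.
#' @return An `augmentation_config` list.
#' @export
augmentation_config <- function(noise_sd = 0.02, channel_drop_range = c(1L, 2L),
                                cutmix_len_range = c(16L, 64L), copies = 2L) {
  stopifnot(noise_sd >= 0, all(channel_drop_range >= 0),
            all(channel_drop_range < 16L),
            cutmix_len_range[1L] >= 1L, copies >= 0L)
  structure(list(noise_sd = noise_sd,
                 channel_drop_range = as.integer(channel_drop_range),
                 cutmix_len_range = as.integer(cutmix_len_range),
                 copies = as.integer(copies)),
            class = "augmentation_config")
}

#' Additive Gaussian jitter
#' @param window L x C matrix.
#' @param noise_sd Noise standard deviation (>= 0).
#' @return Matrix of the same shape.
#' @export
jitter_window <- function(window, noise_sd) {
  if (noise_sd < 0) stop("noise_sd must be nonnegative", call. = FALSE)
  if (noise_sd == 0) return(window)
  window + stats::rnorm(length(window), 0, noise_sd)
}

#' Random channel dropout
#'
#' Draws a count `k` uniformly from `count_range` and zeroes `k` distinct
#' channels (uniform without replacement) across all timesteps.
#'
#' @param window L x C matrix.
#' @param count_range Integer vector of admissible drop counts.
#' @return Matrix with `k` all-zero columns.
#' @export
drop_channels <- function(window, count_range = c(1L, 2L)) {
  stopifnot(all(count_range >= 0L), all(count_range < ncol(window)))
  k <- if (length(count_range) == 1L) count_range else
    count_range[sample.int(length(count_range), 1L)]
  if (k > 0L) {
    ch <- sample.int(ncol(window), k)
    window[, ch] <- 0
  }
  window
}

#' Same-class CutMix
#'
#' Replaces one contiguous timestep interval (all channels) of `window` with
#' the corresponding interval of a same-class `donor` window. The segment
#' length is uniform on `len_range` and the start uniform over valid
#' positions.
#'
#' @param window,donor L x C matrices.
#' @param len_range Segment length range in timesteps.
#' @param window_label,donor_label Optional labels; a mismatch aborts (class
#'   leakage guard).
#' @return Matrix of the same shape.
#' @export
cutmix <- function(window, donor, len_range = c(16L, 64L),
                   window_label = NULL, donor_label = NULL) {
  if (!is.null(window_label) && !is.null(donor_label) &&
      window_label != donor_label) {
    stop("leakage guard [cutmix-class]: donor label differs from window label",
         call. = FALSE)
  }
  stopifnot(all(dim(window) == dim(donor)))
  L <- nrow(window)
  lo <- min(len_range); hi <- min(max(len_range), L)
  len <- if (hi > lo) lo + sample.int(hi - lo + 1L, 1L) - 1L else lo
  s <- if (L - len > 0L) sample.int(L - len + 1L, 1L) else 1L
  idx <- s:(s + len - 1L)
  window[idx, ] <- donor[idx, ]
  window
}

#' Build the augmented training set
#'
#' Appends `copies` augmented copies of every training window, each passing
#' jitter, channel dropout and same-class CutMix in sequence (independent
#' random draws per copy). Originals are retained unmodified and labels and
#' subject ids propagate to the copies. Refuses to run on a batch tagged as
#' validation or test.
#'
#' @param batch A training `window_batch`.
#' @param config An [augmentation_config()].
#' @param seed Integer seed; the result is a pure function of
#'   `(batch, config, seed)`.
#' @return A `window_batch` of size `(1 + copies) * length(batch)`.
#' @export
build_training_set <- function(batch, config = augmentation_config(),
                               seed = 1L) {
  stopifnot(inherits(batch, "window_batch"),
            inherits(config, "augmentation_config"))
  if (!is.na(batch$partition) && batch$partition != "train") {
    stop(sprintf("leakage guard [augment-train-only]: refusing to augment '%s' partition",
                 batch$partition), call. = FALSE)
  }
  if (config$copies == 0L) return(batch)
  set.seed(seed)
  B <- length(batch)
  d <- dim(batch$windows)
  by_class <- split(seq_len(B), batch$labels)
  out <- array(0, c(B * (1L + config$copies), d[2L], d[3L]))
  out[seq_len(B), , ] <- batch$windows
  at <- B
  for (copy in seq_len(config$copies)) {
    for (i in seq_len(B)) {
      w <- batch$windows[i, , ]
      w <- jitter_window(w, config$noise_sd)
      w <- drop_channels(w, config$channel_drop_range)
      pool <- setdiff(by_class[[as.character(batch$labels[i])]], i)
      if (length(pool) > 0L) {
        j <- pool[sample.int(length(pool), 1L)]
        w <- cutmix(w, batch$windows[j, , ], config$cutmix_len_range,
                    batch$labels[i], batch$labels[j])
      }
      out[at + i, , ] <- w
    }
    at <- at + B
  }
  window_batch(out, rep(batch$labels, 1L + config$copies),
               rep(batch$subject_ids, 1L + config$copies), batch$partition)
}
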