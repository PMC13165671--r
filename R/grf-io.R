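# Parsing, subject-stratified splitting, train-only channel standardisation
# and fixed-length windowing.

#' Parse a whitespace-delimited force recording
#'
#' Two dialects are supported. `bare16`: a time column followed by the 16
#' force channels (17 columns). `gaitpdb`: the insole text format — time
#' column, 8 left-foot sensors, 8 right-foot sensors, then two per-foot total
#' columns which are discarded (19 columns). `auto` picks the dialect from
#' the column count.
#'
#' @param path Path to a text file (or a character vector of lines via
#'   `lines`).
#' @param dialect `"auto"`, `"bare16"` or `"gaitpdb"`.
#' @param subject_id,label,sampling_rate Metadata attached to the result.
#' @param lines Optional character vector of raw lines (overrides `path`).
#' @return A [gait_recording()].
#' @export
parse_recording <- function(path = NULL, dialect = c("auto", "bare16", "gaitpdb"),
                            subject_id = NULL, label = NA_integer_,
                            sampling_rate = 100, lines = NULL) {
  dialect <- match.arg(dialect)
  if (is.null(lines)) {
    if (is.null(subject_id)) {
      subject_id <- sub("\\.[^.]*$", "", basename(path))
    }
    lines <- readLines(path)
  } else if (is.null(subject_id)) {
    subject_id <- "stream"
  }
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty recording", call. = FALSE)
  toks <- strsplit(trimws(lines), "[ \t]+")
  ncols <- lengths(toks)
  expect <- ncols[1L]
  bad <- which(ncols != expect)
  if (length(bad) > 0L) {
    stop(sprintf("parse error at line %d: %d columns, expected %d",
                 bad[1L], ncols[bad[1L]], expect), call. = FALSE)
  }
  if (dialect == "auto") {
    dialect <- if (expect == 19L) "gaitpdb" else "bare16"
  }
  need <- if (dialect == "gaitpdb") 19L else 17L
  if (expect != need) {
    # a 17-column file offered as gaitpdb is taken as bare16
    if (dialect == "gaitpdb" && expect == 17L) {
      dialect <- "bare16"; need <- 17L
    } else {
      stop(sprintf("parse error at line 1: %d columns, expected %d for dialect %s",
                   expect, need, dialect), call. = FALSE)
    }
  }
  vals <- suppressWarnings(as.numeric(unlist(toks)))
  if (anyNA(vals)) {
    bad_line <- ceiling(which(is.na(vals))[1L] / expect)
    stop(sprintf("parse error at line %d: non-numeric value", bad_line),
         call. = FALSE)
  }
  m <- matrix(vals, ncol = expect, byrow = TRUE)
  forces <- m[, 2:17, drop = FALSE]
  gait_recording(subject_id, forces, sampling_rate, label)
}

#' Read a `subject_id,label` manifest CSV
#' @param path CSV path with columns `subject_id` and `label`.
#' @return Tibble with character `subject_id` and integer `label`.
#' @export
read_label_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("subject_id", "label") %in% names(df)))
  tibble::tibble(subject_id = as.character(df$subject_id),
                 label = as.integer(df$label))
}

#' Read a cohort directory written by [write_cohort()]
#' @param dir Directory with per-subject `.txt` files and `manifest.csv`.
#' @param sampling_rate Hz.
#' @return A `grf_cohort`.
#' @export
read_cohort <- function(dir, sampling_rate = 100) {
  manifest <- read_label_manifest(file.path(dir, "manifest.csv"))
  recs <- purrr::map2(manifest$subject_id, manifest$label, function(id, lb) {
    parse_recording(file.path(dir, paste0(id, ".txt")), subject_id = id,
                    label = lb, sampling_rate = sampling_rate)
  })
  structure(list(recordings = recs, manifest = manifest), class = "grf_cohort")
}

#' Subject-stratified train/validation/test split
#'
#' Allocates subjects of each class to the three partitions by
#' largest-remainder rounding of `n_class * fraction` (surplus seats go to
#' the largest fractional remainders, ties broken in partition order), then
#' assigns shuffled subjects deterministically under `seed`. Every partition
#' must receive at least one subject of each class.
#'
#' @param labels Tibble/data frame with columns `subject_id` and `label`, or
#'   a named 0/1 vector.
#' @param fractions Train/validation/test fractions summing to 1.
#' @param seed Integer seed.
#' @return Tibble (`split_spec`) with columns `subject_id`, `label`,
#'   `partition` (factor train/val/test).
#' @export
stratified_subject_split <- function(labels, fractions = c(0.70, 0.15, 0.15),
                                     seed = 1L) {
  if (!is.data.frame(labels)) {
    labels <- tibble::tibble(subject_id = names(labels),
                             label = as.integer(labels))
  }
  stopifnot(abs(sum(fractions) - 1) < 1e-9, length(fractions) == 3L)
  parts <- c("train", "val", "test")
  if (length(unique(labels$label)) < 2L) {
    stop("both classes must be present for a stratified split", call. = FALSE)
  }
  set.seed(seed)
  out <- list()
  for (cl in sort(unique(labels$label))) {
    ids <- labels$subject_id[labels$label == cl]
    n <- length(ids)
    quota <- n * fractions
    base <- floor(quota)
    seats <- n - sum(base)
    if (seats > 0L) {
      rem <- quota - base
      extra <- order(-rem, seq_along(rem))[seq_len(seats)]
      base[extra] <- base[extra] + 1L
    }
    if (any(base == 0L)) {
      stop(sprintf(
        "configuration error: class %s would leave a partition empty (counts %s)",
        cl, paste(base, collapse = "/")), call. = FALSE)
    }
    ids <- sample(ids)
    assign <- rep(parts, times = base)
    out[[as.character(cl)]] <- tibble::tibble(
      subject_id = ids, label = cl, partition = assign)
  }
  res <- dplyr::arrange(dplyr::bind_rows(out), .data$subject_id)
  res$partition <- factor(res$partition, levels = parts)
  class(res) <- c("split_spec", class(res))
  res
}

#' Fit the per-channel standardiser on training recordings
#'
#' Computes the empirical mean and population standard deviation of each of
#' the 16 channels over the concatenation of all training frames. Standard
#' deviations are floored at `1e-8`. The returned scaler is a frozen value
#' object: apply it to validation/test data, never refit.
#'
#' @param recordings List of [gait_recording()]s (the training partition).
#' @return A `channel_scaler` with fields `mean` and `sd`.
#' @export
fit_channel_scaler <- function(recordings) {
  if (inherits(recordings, "gait_recording")) recordings <- list(recordings)
  if (length(recordings) == 0L) stop("no training recordings", call. = FALSE)
  X <- do.call(rbind, lapply(recordings, function(r) r$forces))
  if (nrow(X) < 1L) stop("no training frames", call. = FALSE)
  mu <- colMeans(X)
  sd <- sqrt(colMeans(sweep(X, 2L, mu, "-")^2))
  sd <- pmax(sd, 1e-8)
  structure(list(mean = mu, sd = sd), class = "channel_scaler")
}

#' Apply a fitted channel scaler
#' @param x A [gait_recording()], a list of them, or a T x 16 matrix.
#' @param scaler A `channel_scaler`.
#' @return Object of the same shape with z-scored forces.
#' @export
apply_scaler <- function(x, scaler) {
  stopifnot(inherits(scaler, "channel_scaler"))
  zs <- function(m) sweep(sweep(m, 2L, scaler$mean, "-"), 2L, scaler$sd, "/")
  if (inherits(x, "gait_recording")) {
    x$forces <- zs(x$forces)
    return(x)
  }
  if (is.list(x)) return(lapply(x, apply_scaler, scaler = scaler))
  zs(x)
}

#' Construct a window batch
#' @param windows B x L x C array.
#' @param labels,subject_ids Per-window metadata (length B).
#' @param partition Optional partition tag ("train", "val", "test").
#' @return A `window_batch`.
#' @export
window_batch <- function(windows, labels, subject_ids, partition = NA_character_) {
  stopifnot(length(dim(windows)) == 3L,
            dim(windows)[1L] == length(labels),
            length(labels) == length(subject_ids))
  structure(list(windows = windows, labels = as.integer(labels),
                 subject_ids = as.character(subject_ids),
                 partition = partition),
            class = "window_batch")
}

#' @export
print.window_batch <- function(x, ...) {
  d <- dim(x$windows)
  cat(sprintf("<window_batch> %d windows of %d x %d (%d subjects%s)\n",
              d[1L], d[2L], d[3L], length(unique(x$subject_ids)),
              if (is.na(x$partition)) "" else paste0(", ", x$partition)))
  invisible(x)
}

#' @export
length.window_batch <- function(x) dim(x$windows)[1L]

#' Cut a recording into fixed-length windows
#'
#' Half-open windows `[s, s + length)` at 0-based starts `0, stride, ...`;
#' the window count is `floor((T - length) / stride) + 1` for `T >= length`
#' and 0 otherwise (trailing partial windows are discarded, with a warning
#' when a recording is too short to yield any window).
#'
#' @param recording A [gait_recording()] (typically standardised).
#' @param length Window length in timesteps.
#' @param stride Hop between window starts.
#' @param partition Optional partition tag propagated to the batch.
#' @return A `window_batch`; every window carries the subject's id and label.
#' @export
segment_windows <- function(recording, length = 128L, stride = 64L,
                            partition = NA_character_) {
  stopifnot(inherits(recording, "gait_recording"), length >= 1L, stride >= 1L)
  Tn <- nrow(recording$forces)
  n <- if (Tn >= length) (Tn - length) %/% stride + 1L else 0L
  if (n == 0L) {
    warning(sprintf("recording %s has %d frames, shorter than one window (%d)",
                    recording$subject_id, Tn, length))
    return(window_batch(array(0, c(0L, length, 16L)), integer(0), character(0),
                        partition))
  }
  w <- array(0, c(n, length, 16L))
  for (i in seq_len(n)) {
    s <- (i - 1L) * stride
    w[i, , ] <- recording$forces[(s + 1L):(s + length), ]
  }
  window_batch(w, rep(recording$label, n), rep(recording$subject_id, n),
               partition)
}

#' Concatenate window batches
#' @param batches List of `window_batch` objects with matching window shape.
#' @param partition Partition tag of the result.
#' @return A single `window_batch`.
#' @export
bind_window_batches <- function(batches, partition = NA_character_) {
  batches <- batches[vapply(batches, length, 0L) > 0L]
  if (length(batches) == 0L) stop("no non-empty batches", call. = FALSE)
  d <- dim(batches[[1L]]$windows)
  n <- sum(vapply(batches, length, 0L))
  w <- array(0, c(n, d[2L], d[3L]))
  at <- 0L
  for (b in batches) {
    nb <- length(b)
    w[(at + 1L):(at + nb), , ] <- b$windows
    at <- at + nb
  }
  window_batch(w,
               unlist(lapply(batches, `[[`, "labels")),
               unlist(lapply(batches, `[[`, "subject_ids")),
               partition)
}

#' Window all recordings of one split partition
#'
#' @param recordings List of (standardised) [gait_recording()]s.
#' @param split A `split_spec` from [stratified_subject_split()].
#' @param partition `"train"`, `"val"` or `"test"`.
#' @param length,stride Windowing parameters.
#' @return A `window_batch` for the partition.
#' @export
segment_partition <- function(recordings, split, partition,
                              length = 128L, stride = 64L) {
  ids <- split$subject_id[split$partition == partition]
  recs <- Filter(function(r) r$subject_id %in% ids, recordings)
  if (length(recs) == 0L) stop(sprintf("partition %s has no recordings",
                                       partition), call. = FALSE)
  bind_window_batches(lapply(recs, segment_windows, length = length,
                             stride = stride), partition)
}

#' Assert that window batches share no subjects
#'
#' The subject-level leakage guard: any subject appearing in two partitions
#' aborts with an error naming the guard.
#'
#' @param ... `window_batch` objects.
#' @return Invisibly `TRUE`.
#' @export
assert_disjoint_subjects <- function(...) {
  bs <- list(...)
  for (i in seq_along(bs)) {
    for (j in seq_len(i - 1L)) {
      inter <- intersect(unique(bs[[i]]$subject_ids),
                         unique(bs[[j]]$subject_ids))
      if (length(inter) > 0L) {
        stop(sprintf("leakage guard [subject-disjointness]: subjects shared across partitions: %s",
                     paste(inter, collapse = ", ")), call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}
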