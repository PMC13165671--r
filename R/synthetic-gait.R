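# Synthetic ground-reaction-force cohorts.
#
# Each recording is a T x 16 matrix of vertical plantar forces at `sampling
# rate` Hz: channels 1-8 are the left foot, 9-16 the right foot, each foot
# carrying (heel, midfoot, midfoot, forefoot, forefoot, forefoot, toe, toe)
# sensors. Strides are quasi-periodic; within each stance phase (62% of the
# stride) every anatomical region is active over a half-cosine window placed
# at its canonical phase: heel in early stance, midfoot mid-stance, forefoot
# late stance, toe at push-off. Parkinsonian recordings carry reduced
# push-off amplitude, elevated stride-interval variability, a prolonged
# midfoot window, and bilateral amplitude asymmetry.

REGION_ORDER <- c("heel", "midfoot", "forefoot", "toe")

# per-foot channel -> region mapping (overridable wherever it is consumed)
#' Default channel-to-region assignment for one foot
#' @return Character vector of length 8 of region names.
#' @export
foot_region_map <- function() {
  c("heel", "midfoot", "midfoot", "forefoot", "forefoot", "forefoot",
    "toe", "toe")
}

# fixed per-channel gains so sensors within a region are distinguishable
CHANNEL_GAIN <- c(1, 1, 0.9, 1, 0.95, 0.9, 1, 0.9)

# region activation windows as fractions of stance, and base amplitudes
REGION_WINDOW <- list(heel = c(0.00, 0.30), midfoot = c(0.20, 0.60),
                      forefoot = c(0.40, 0.85), toe = c(0.60, 1.00))
REGION_AMP <- c(heel = 1.0, midfoot = 0.6, forefoot = 0.9, toe = 0.8)
STANCE_FRAC <- 0.62

#' Synthetic cohort configuration
#'
#' Study-condition defaults: 28 PD + 12 healthy subjects, 60 s of walking at
#' 100 Hz, stride periods 0.95 s (PD) / 1.05 s (HC) with coefficients of
#' variation 0.08 / 0.03, 35% push-off amplitude reduction, 30% midfoot
#' window prolongation and 15% bilateral amplitude asymmetry in the PD class,
#' log-normal between-subject random effects and additive sensor noise.
#'
#' @param n_pd,n_hc Subjects per class (each at least 1 unless generating a
#'   single-class cohort).
#' @param duration_s Recording duration in seconds.
#' @param sampling_rate Sampling rate in Hz.
#' @param stride_period_mean Named or ordered pair `(pd, hc)` of mean stride
#'   periods in seconds.
#' @param stride_cv Pair `(pd, hc)` of stride-interval coefficients of
#'   variation.
#' @param pushoff_reduction Fractional reduction of PD toe/forefoot
#'   amplitude, in `[0, 1)`.
#' @param midfoot_prolongation Fractional widening of the PD midfoot
#'   activation window, in `[0, 1)`.
#' @param asymmetry Fractional left/right amplitude imbalance for PD, in
#'   `[0, 1)`.
#' @param subject_sd Scale of the log-normal between-subject random effects.
#' @param noise_sd Standard deviation of additive sensor noise.
#' @param seed Integer seed; identical config and seed give a bit-identical
#'   cohort.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_pd = 28L, n_hc = 12L, duration_s = 60,
                          sampling_rate = 100,
                          stride_period_mean = c(pd = 0.95, hc = 1.05),
                          stride_cv = c(pd = 0.08, hc = 0.03),
                          pushoff_reduction = 0.35,
                          midfoot_prolongation = 0.3,
                          asymmetry = 0.15, subject_sd = 0.1,
                          noise_sd = 0.05, seed = 1L) {
  fr <- c(pushoff_reduction, midfoot_prolongation, asymmetry)
  if (any(fr < 0) || any(fr >= 1)) {
    stop("effect fractions must lie in [0, 1)", call. = FALSE)
  }
  if (sampling_rate <= 0 || duration_s <= 0) {
    stop("duration and sampling rate must be positive", call. = FALSE)
  }
  if (n_pd < 0 || n_hc < 0 || n_pd + n_hc < 1) {
    stop("need at least one subject", call. = FALSE)
  }
  if (subject_sd < 0 || noise_sd < 0 || any(stride_cv < 0)) {
    stop("scales must be nonnegative", call. = FALSE)
  }
  structure(list(
    n_pd = as.integer(n_pd), n_hc = as.integer(n_hc),
    duration_s = duration_s, sampling_rate = sampling_rate,
    stride_period_mean = unname(stride_period_mean),
    stride_cv = unname(stride_cv),
    pushoff_reduction = pushoff_reduction,
    midfoot_prolongation = midfoot_prolongation,
    asymmetry = asymmetry, subject_sd = subject_sd,
    noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Construct a gait recording object
#' @param subject_id Identifier.
#' @param forces T x 16 numeric matrix of forces.
#' @param sampling_rate Hz.
#' @param label 0 (healthy) or 1 (PD).
#' @return A `gait_recording`.
#' @export
gait_recording <- function(subject_id, forces, sampling_rate, label) {
  forces <- as.matrix(forces)
  if (ncol(forces) != 16L) stop("forces must have exactly 16 channels",
                                call. = FALSE)
  if (nrow(forces) < 1L || !all(is.finite(forces))) {
    stop("forces must be non-empty and finite", call. = FALSE)
  }
  structure(list(subject_id = as.character(subject_id), forces = forces,
                 sampling_rate = sampling_rate, label = as.integer(label)),
            class = "gait_recording")
}

#' @export
print.gait_recording <- function(x, ...) {
  cat(sprintf("<gait_recording> subject %s: %d frames x 16 channels @ %g Hz, label %d\n",
              x$subject_id, nrow(x$forces), x$sampling_rate, x$label))
  invisible(x)
}

# realised per-subject generation parameters
subject_profile <- function(label, config) {
  amp_mult <- exp(stats::rnorm(1L, 0, config$subject_sd))
  per_mult <- exp(stats::rnorm(1L, 0, config$subject_sd / 2))
  cls <- if (label == 1L) 1L else 2L
  amps <- REGION_AMP
  widen <- 1
  asym <- 0
  if (label == 1L) {
    amps[c("forefoot", "toe")] <- amps[c("forefoot", "toe")] *
      (1 - config$pushoff_reduction)
    widen <- 1 + config$midfoot_prolongation
    asym <- config$asymmetry
  }
  list(period = config$stride_period_mean[cls] * per_mult,
       cv = config$stride_cv[cls],
       amps = amps * amp_mult, midfoot_widen = widen, asymmetry = asym)
}

#' Generate one synthetic gait recording
#'
#' Renders the quasi-periodic stance template of a single subject: stride
#' intervals are drawn i.i.d. from a truncated normal with the subject's
#' period mean and coefficient of variation, and each anatomical region
#' contributes a half-cosine force bump at its stance phase. Forces are
#' nonnegative before noise is added.
#'
#' @param profile List with `period` (s), `cv`, `amps` (named region
#'   amplitudes), `midfoot_widen`, `asymmetry`; see [cohort_config()].
#' @param duration_s,sampling_rate Recording length and rate.
#' @param noise_sd Additive sensor noise standard deviation.
#' @param subject_id,label Metadata for the returned recording.
#' @return A [gait_recording()] with `duration_s * sampling_rate` frames.
#' @export
generate_recording <- function(profile, duration_s, sampling_rate,
                               noise_sd = 0, subject_id = "s1", label = 0L) {
  if (duration_s <= 0 || sampling_rate <= 0) {
    stop("duration and sampling rate must be positive", call. = FALSE)
  }
  Tn <- as.integer(round(duration_s * sampling_rate))
  forces <- matrix(0, Tn, 16L)
  tgrid <- (seq_len(Tn) - 1L) / sampling_rate

  n_max <- ceiling(duration_s / profile$period * 1.6) + 4L
  intervals <- stats::rnorm(n_max, profile$period, profile$cv * profile$period)
  intervals <- pmax(intervals, 0.3 * profile$period)
  onsets <- cumsum(c(0, intervals))

  regions <- foot_region_map()
  for (foot in 1:2) {
    side_mult <- if (foot == 1L) 1 + profile$asymmetry / 2 else
      1 - profile$asymmetry / 2
    phase <- if (foot == 1L) 0 else profile$period / 2
    ch0 <- (foot - 1L) * 8L
    for (j in seq_along(intervals)) {
      o <- onsets[j] + phase
      stance <- STANCE_FRAC * intervals[j]
      if (o > duration_s) break
      for (r in REGION_ORDER) {
        win <- REGION_WINDOW[[r]]
        if (r == "midfoot" && profile$midfoot_widen != 1) {
          ctr <- mean(win); hw <- diff(win) / 2 * profile$midfoot_widen
          win <- c(max(0, ctr - hw), min(1, ctr + hw))
        }
        t0 <- o + win[1L] * stance
        len <- (win[2L] - win[1L]) * stance
        i0 <- max(1L, ceiling(t0 * sampling_rate) + 1L)
        i1 <- min(Tn, floor((t0 + len) * sampling_rate) + 1L)
        if (i1 < i0) next
        bump <- sin(pi * (tgrid[i0:i1] - t0) / len)
        bump[bump < 0] <- 0
        amp <- profile$amps[[r]] * side_mult
        for (ch in which(regions == r)) {
          forces[i0:i1, ch0 + ch] <- forces[i0:i1, ch0 + ch] +
            amp * CHANNEL_GAIN[ch] * bump
        }
      }
    }
  }
  if (noise_sd > 0) {
    forces <- forces + stats::rnorm(length(forces), 0, noise_sd)
  }
  gait_recording(subject_id, forces, sampling_rate, label)
}

#' Generate a labelled synthetic cohort
#'
#' Draws per-subject random effects and renders one recording per subject
#' under the configured class-dependent gait signatures. Deterministic given
#' the config seed.
#'
#' @param config A [cohort_config()].
#' @return A `grf_cohort`: list with `recordings` (list of
#'   [gait_recording()]) and `manifest` (tibble `subject_id`, `label`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  labels <- c(rep(1L, config$n_pd), rep(0L, config$n_hc))
  ids <- sprintf("subj%03d", seq_along(labels))
  recs <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    prof <- subject_profile(labels[i], config)
    recs[[i]] <- generate_recording(prof, config$duration_s,
                                    config$sampling_rate,
                                    noise_sd = config$noise_sd,
                                    subject_id = ids[i], label = labels[i])
  }
  structure(list(recordings = recs,
                 manifest = tibble::tibble(subject_id = ids, label = labels)),
            class = "grf_cohort")
}

#' @export
print.grf_cohort <- function(x, ...) {
  cat(sprintf("<grf_cohort> %d subjects (%d PD / %d HC)\n",
              nrow(x$manifest), sum(x$manifest$label == 1L),
              sum(x$manifest$label == 0L)))
  invisible(x)
}

#' Write a cohort as whitespace-delimited text files
#'
#' One file per subject in the bare 17-column dialect (time column plus 16
#' force channels) that [parse_recording()] reads, plus a CSV label manifest
#' (`subject_id,label`).
#'
#' @param cohort A `grf_cohort`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "grf_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rec in cohort$recordings) {
    tt <- (seq_len(nrow(rec$forces)) - 1L) / rec$sampling_rate
    utils::write.table(cbind(tt, rec$forces),
                       file.path(dir, paste0(rec$subject_id, ".txt")),
                       row.names = FALSE, col.names = FALSE)
  }
  mf <- file.path(dir, "manifest.csv")
  utils::write.csv(cohort$manifest, mf, row.names = FALSE)
  invisible(mf)
}
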