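# Shared helpers for the test suite.

# A deliberately small architecture for fast exact checks (gradient checks,
# shape tests). Penalties on, dropout off so losses are deterministic.
tiny_senn_config <- function(...) {
  senn_config(K = 3L, filters = c(3L, 4L, 4L, 5L), kernel_size = 3L,
              p_L = 0, spatial_dropout = 0, gap_dropout = 0,
              dense_dropout = 0, l2 = 1e-3, window = 16L,
              input_channels = 2L, relevance_units = c(6L, 5L),
              head_units = 4L, ...)
}

# A small separable two-class window problem for training smoke tests:
# class 1 carries an offset sinusoid on channel 1.
toy_problem <- function(n_per_class = 30L, window = 16L, channels = 2L,
                        subjects_per_class = 3L, partition = NA_character_,
                        seed = 1L) {
  set.seed(seed)
  n <- 2L * n_per_class
  w <- array(stats::rnorm(n * window * channels, 0, 0.3),
             c(n, window, channels))
  labels <- rep(c(0L, 1L), each = n_per_class)
  tgrid <- seq_len(window) / window
  for (i in which(labels == 1L)) {
    w[i, , 1L] <- w[i, , 1L] + 1.5 * sin(2 * pi * tgrid)
  }
  subj <- paste0("s", labels, "_",
                 rep_len(seq_len(subjects_per_class), n_per_class))
  window_batch(w, labels, subj, partition)
}

# The small cohort/optimizer scale used by the end-to-end unit and ablation
# tests (chosen for runtime; class ratio matches the default cohort).
tiny_cohort_config <- function(seed = 1L) {
  cohort_config(n_pd = 14L, n_hc = 6L, duration_s = 10, seed = seed)
}

tiny_optimizer <- function(t_max = 4L) {
  optimizer_spec(t_max = t_max, warmup = 1L)
}
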