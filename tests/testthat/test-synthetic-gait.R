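test_that("cohort_config validates its arguments", {
  expect_error(cohort_config(pushoff_reduction = 1.2), "effect fractions")
  expect_error(cohort_config(asymmetry = -0.1), "effect fractions")
  expect_error(cohort_config(duration_s = 0), "positive")
  expect_error(cohort_config(n_pd = 0, n_hc = 0), "at least one subject")
  expect_error(cohort_config(noise_sd = -1), "nonnegative")
})

test_that("generate_cohort is deterministic and correctly shaped", {
  cc <- cohort_config(n_pd = 3L, n_hc = 2L, duration_s = 4, seed = 9L)
  a <- generate_cohort(cc)
  b <- generate_cohort(cc)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$recordings[[1L]]$forces, b$recordings[[1L]]$forces)
  expect_equal(nrow(a$manifest), 5L)
  expect_equal(sum(a$manifest$label), 3L)
  for (r in a$recordings) {
    expect_equal(dim(r$forces), c(400L, 16L))
    expect_true(all(is.finite(r$forces)))
  }
  # a different seed gives different data
  c2 <- generate_cohort(cohort_config(n_pd = 3L, n_hc = 2L, duration_s = 4,
                                      seed = 10L))
  expect_false(identical(a$recordings[[1L]]$forces,
                         c2$recordings[[1L]]$forces))
})

test_that("the parkinsonian signature is present in noise-free recordings", {
  base <- list(period = 1.0, cv = 0, amps = c(heel = 1.0, midfoot = 0.6,
                                              forefoot = 0.9, toe = 0.8),
               midfoot_widen = 1, asymmetry = 0)
  pd <- base
  pd$amps[c("forefoot", "toe")] <- pd$amps[c("forefoot", "toe")] * (1 - 0.35)
  pd$midfoot_widen <- 1.3
  pd$asymmetry <- 0.15
  hc_rec <- generate_recording(base, 20, 100, noise_sd = 0)$forces
  pd_rec <- generate_recording(pd, 20, 100, noise_sd = 0)$forces

  toe <- c(7L, 8L, 15L, 16L)
  mid <- c(2L, 3L, 10L, 11L)
  # push-off reduction: toe force mass shrinks by the configured fraction
  expect_lt(sum(pd_rec[, toe]), 0.75 * sum(hc_rec[, toe]))
  # midfoot prolongation: midfoot channels are active for longer
  expect_gt(mean(pd_rec[, mid] > 0.05), mean(hc_rec[, mid] > 0.05))
  # bilateral asymmetry: left amplitude exceeds right by (1+a/2)/(1-a/2)
  left_heel <- sum(pd_rec[, 1L])
  right_heel <- sum(pd_rec[, 9L])
  expect_equal(left_heel / right_heel, (1 + 0.15 / 2) / (1 - 0.15 / 2),
               tolerance = 0.05)
  # the healthy template is symmetric
  expect_equal(sum(hc_rec[, 1L]) / sum(hc_rec[, 9L]), 1, tolerance = 0.05)
  # forces are nonnegative before noise
  expect_true(all(hc_rec >= 0) && all(pd_rec >= 0))
})

test_that("write_cohort / read_cohort round-trips", {
  cc <- cohort_config(n_pd = 2L, n_hc = 1L, duration_s = 2, seed = 3L)
  cohort <- generate_cohort(cc)
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  back <- read_cohort(dir)
  expect_identical(back$manifest$label, cohort$manifest$label)
  expect_identical(back$manifest$subject_id, cohort$manifest$subject_id)
  for (i in seq_along(cohort$recordings)) {
    expect_equal(back$recordings[[i]]$forces,
                 cohort$recordings[[i]]$forces, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})
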