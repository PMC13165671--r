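test_that("the three augmentation stages behave as specified", {
  w <- matrix(stats::rnorm(128 * 16), 128L, 16L)
  expect_identical(jitter_window(w, 0), w)
  set.seed(1)
  j <- jitter_window(w, 0.02)
  expect_equal(sd(j - w), 0.02, tolerance = 0.1)

  set.seed(2)
  d <- drop_channels(w, c(1L, 2L))
  zeroed <- which(colSums(d == 0) == nrow(d))
  expect_true(length(zeroed) %in% 1:2)
  expect_identical(d[, -zeroed], w[, -zeroed])

  donor <- matrix(100, 128L, 16L)
  set.seed(3)
  cm <- cutmix(w, donor, c(16L, 64L))
  seg <- which(rowSums(cm == 100) == 16L)
  expect_true(length(seg) >= 16L && length(seg) <= 64L)
  expect_identical(seg, seg[1L]:(seg[1L] + length(seg) - 1L))  # contiguous
  expect_identical(cm[-seg, ], w[-seg, ])
  expect_error(cutmix(w, donor, window_label = 1L, donor_label = 0L),
               "leakage guard \\[cutmix-class\\]")
})

test_that("build_training_set appends seeded same-class copies", {
  batch <- toy_problem(n_per_class = 5L, channels = 16L, partition = "train")
  cfg <- augmentation_config(copies = 2L)
  a <- build_training_set(batch, cfg, seed = 4L)
  expect_equal(length(a), 3L * length(batch))
  expect_identical(a$windows[seq_len(length(batch)), , ], batch$windows)
  expect_identical(a$labels, rep(batch$labels, 3L))
  expect_identical(a$subject_ids, rep(batch$subject_ids, 3L))
  b <- build_training_set(batch, cfg, seed = 4L)
  expect_identical(a$windows, b$windows)
  expect_false(identical(a$windows,
                         build_training_set(batch, cfg, seed = 5L)$windows))
  # copies differ from the originals
  expect_false(identical(a$windows[length(batch) + 1L, , ],
                         batch$windows[1L, , ]))
})

test_that("augmentation refuses non-training partitions", {
  val <- toy_problem(n_per_class = 2L, channels = 16L, partition = "val")
  expect_error(build_training_set(val, augmentation_config(), 1L),
               "leakage guard \\[augment-train-only\\]")
  untagged <- toy_problem(n_per_class = 2L, channels = 16L)
  expect_s3_class(build_training_set(untagged, augmentation_config(), 1L),
                  "window_batch")
})
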