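test_that("parse_recording handles both dialects and reports bad lines", {
  mk_lines <- function(m) apply(m, 1L, paste, collapse = " ")
  m17 <- cbind(0:2 / 100, matrix(seq_len(48), 3L, 16L))
  rec <- parse_recording(lines = mk_lines(m17), subject_id = "a", label = 1L)
  expect_s3_class(rec, "gait_recording")
  expect_equal(dim(rec$forces), c(3L, 16L))
  expect_equal(rec$forces[2L, 5L], m17[2L, 6L])

  # gaitpdb: 19 columns, the two trailing per-foot totals are discarded
  m19 <- cbind(m17, rowSums(m17[, 2:9]), rowSums(m17[, 10:17]))
  rec19 <- parse_recording(lines = mk_lines(m19), dialect = "gaitpdb")
  expect_equal(rec19$forces, rec$forces, ignore_attr = TRUE)

  ragged <- c("1 2 3", "1 2")
  expect_error(parse_recording(lines = ragged), "line 2")
  bad <- mk_lines(m17)
  bad[3L] <- sub("33", "x", bad[3L])
  expect_error(parse_recording(lines = bad), "line 3.*non-numeric")
})

test_that("stratified split keeps classes proportional and is seeded", {
  labels <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:40),
    label = rep(c(1L, 0L), c(28L, 12L)))
  sp <- stratified_subject_split(labels, c(0.70, 0.15, 0.15), seed = 5L)
  tab <- table(sp$label, sp$partition)
  # largest-remainder quotas: 28 -> 20/4/4, 12 -> 8/2/2
  expect_equal(unname(tab["1", ]), c(20L, 4L, 4L))
  expect_equal(unname(tab["0", ]), c(8L, 2L, 2L))
  expect_setequal(sp$subject_id, labels$subject_id)
  expect_identical(sp, stratified_subject_split(labels, seed = 5L))
  expect_false(identical(sp$partition[order(sp$subject_id)],
                         stratified_subject_split(labels, seed = 6L)$partition[
                           order(sp$subject_id)]))
  # a class too small to cover all three partitions aborts
  tiny <- tibble::tibble(subject_id = c("a", "b", "c"),
                         label = c(1L, 1L, 0L))
  expect_error(stratified_subject_split(tiny), "empty")
})

test_that("channel scaler matches the population oracle and freezes", {
  r1 <- gait_recording("a", matrix(c(1, 3, rep(0, 30)), 2L, 16L), 100, 0L)
  r2 <- gait_recording("b", matrix(c(5, 7, rep(0, 30)), 2L, 16L), 100, 1L)
  sc <- fit_channel_scaler(list(r1, r2))
  x <- c(1, 3, 5, 7)
  expect_equal(sc$mean[1L], mean(x))
  expect_equal(sc$sd[1L], sqrt(mean((x - mean(x))^2)))  # population sd
  expect_equal(sc$sd[2L], 1e-8)                          # constant channel floor
  z <- apply_scaler(list(r1, r2), sc)
  pooled <- rbind(z[[1L]]$forces, z[[2L]]$forces)[, 1L]
  expect_equal(mean(pooled), 0)
  expect_equal(sqrt(mean(pooled^2)), 1)
})

test_that("windowing follows the floor count formula and guards leakage", {
  rec <- gait_recording("a", matrix(seq_len(300 * 16), 300L, 16L), 100, 1L)
  wb <- segment_windows(rec, length = 128L, stride = 64L)
  expect_equal(length(wb), (300L - 128L) %/% 64L + 1L)  # = 3
  expect_equal(wb$windows[2L, 1L, 1L], rec$forces[65L, 1L])
  expect_equal(wb$windows[2L, 128L, 16L], rec$forces[192L, 16L])
  expect_equal(wb$labels, rep(1L, 3L))

  short <- gait_recording("b", matrix(0, 100L, 16L), 100, 0L)
  expect_warning(empty <- segment_windows(short, 128L, 64L), "shorter")
  expect_equal(length(empty), 0L)

  wb2 <- segment_windows(gait_recording("b", matrix(0, 200L, 16L), 100, 0L))
  both <- bind_window_batches(list(wb, wb2))
  expect_equal(length(both), 5L)
  expect_equal(both$subject_ids, c("a", "a", "a", "b", "b"))

  expect_error(assert_disjoint_subjects(wb, wb),
               "leakage guard \\[subject-disjointness\\].*a")
  expect_true(assert_disjoint_subjects(wb, wb2))
})
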