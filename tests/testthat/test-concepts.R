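test_that("sensor groups follow the per-foot region layout", {
  g <- sensor_group_map()
  expect_length(g, 16L)
  expect_equal(g[1L], "left_heel")
  expect_equal(g[9L], "right_heel")
  expect_equal(sort(unique(g)),
               sort(as.vector(outer(c("left", "right"),
                                    c("heel", "midfoot", "forefoot", "toe"),
                                    paste, sep = "_"))))
  expect_error(sensor_group_map(c("heel", "toe")), "length")
})

test_that("discriminative statistics match hand oracles", {
  contrib <- cbind(c(1, 2, 0, 1), c(5, 5, 5, 5))
  labels <- c(1L, 1L, 0L, 0L)
  st <- discriminative_stats(contrib, labels)
  # concept 1: means 1.5 vs 0.5, both variances 0.5 -> pooled sqrt(0.5)
  expect_equal(st$delta[1L], 1)
  expect_equal(st$cohens_d[1L], 1 / sqrt(0.5))
  expect_false(st$zero_spread[1L])
  # concept 2: constant -> zero pooled spread, delta 0, signed infinite d
  expect_equal(st$delta[2L], 0)
  expect_true(st$zero_spread[2L])
  # a constant shift separates the sign
  st2 <- discriminative_stats(cbind(c(2, 2, 1, 1)), labels)
  expect_equal(st2$cohens_d[1L], Inf)
  st3 <- discriminative_stats(cbind(c(1, 1, 2, 2)), labels)
  expect_equal(st3$cohens_d[1L], -Inf)
  expect_error(discriminative_stats(contrib, c(1L, 1L, 1L, 1L)),
               "both classes")
})

test_that("concept-sensor correlation recovers a planted alignment", {
  set.seed(21)
  B <- 40L
  raw <- array(stats::rnorm(B * 8 * 16, 1, 0.2), c(B, 8L, 16L))
  gmap <- sensor_group_map()
  heel_mean <- rowMeans(matrix(raw[, , gmap == "left_heel"], B))
  h <- cbind(heel_mean, stats::rnorm(B))
  r <- concept_sensor_correlation(h, raw, gmap)
  expect_equal(dim(r), c(2L, 8L))
  expect_equal(unname(r[1L, "left_heel"]), 1)
  expect_lt(abs(r[2L, "left_heel"]), 0.5)
  expect_false(attr(r, "zero_variance"))
  # a constant concept column is flagged and zeroed
  r0 <- concept_sensor_correlation(cbind(rep(1, B), heel_mean), raw, gmap)
  expect_true(attr(r0, "zero_variance"))
  expect_equal(unname(r0[1L, ]), rep(0, 8L))
})

test_that("concept_report ranks by class gap and verifies the identity", {
  set.seed(22)
  B <- 20L; K <- 4L
  outputs <- list(h_tilde = matrix(stats::rnorm(B * K), B, K),
                  theta = matrix(stats::rnorm(B * K), B, K))
  outputs$z <- rowSums(outputs$h_tilde * outputs$theta)
  labels <- rep(c(0L, 1L), each = 10L)
  rep_ <- concept_report(outputs, labels, top_m = 2L,
                         subject_ids = rep(c("a", "b"), 10L))
  expect_s3_class(rep_, "concept_report")
  expect_equal(rep_$ranking, order(-rep_$stats$delta, rep_$stats$concept))
  expect_equal(nrow(rep_$explanations), B * 2L)
  expect_equal(rep_$explanations$rank, rep(1:2, B))
  # per-window top contributions are ordered by absolute magnitude
  first <- rep_$explanations[rep_$explanations$window == 1L, ]
  expect_gte(abs(first$contribution[1L]), abs(first$contribution[2L]))
  expect_s3_class(tidy(rep_), "tbl_df")
  expect_s3_class(ggplot2::autoplot(rep_), "ggplot")
  # a corrupted aggregate violates the structural identity guard
  bad <- outputs
  bad$z <- bad$z + 1
  expect_error(concept_report(bad, labels))
})
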