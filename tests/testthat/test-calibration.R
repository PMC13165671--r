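test_that("temperature scaling is monotone and identity at T = 1", {
  p <- c(0.1, 0.4, 0.7, 0.95)
  expect_identical(apply_temperature(p, 1), p)
  q <- apply_temperature(p, 2)
  expect_true(all(diff(q) > 0))
  expect_true(all(abs(q - 0.5) < abs(p - 0.5)))  # T > 1 softens
  expect_error(apply_temperature(p, 0))
})

test_that("fit_temperature recovers a planted mis-scaling", {
  set.seed(123)
  lg <- stats::rnorm(4000, 0, 2)
  y <- stats::rbinom(4000, 1L, 1 / (1 + exp(-lg)))
  over <- 1 / (1 + exp(-2 * lg))      # logits doubled: overconfident
  sc <- fit_temperature(over, y)
  expect_equal(sc$T, 2, tolerance = 0.1)
  expect_lte(sc$fit_nll, sc$nll_at_unit)
  expect_error(fit_temperature(c(0.2, 0.8), c(1, 1)), "both classes")
})

test_that("subject pooling averages windows in first-appearance order", {
  p <- c(0.2, 0.4, 0.9, 0.1, 0.3)
  ids <- c("b", "b", "a", "b", "a")
  sp <- pool_subject_probabilities(p, ids)
  expect_equal(names(sp), c("b", "a"))
  expect_equal(unname(sp), c(mean(c(0.2, 0.4, 0.1)), mean(c(0.9, 0.3))))
})

test_that("threshold selection maximises macro-F1 with a largest-tau tie-break", {
  probs <- c(a = 0.15, b = 0.25, c = 0.80, d = 0.90)
  labels <- c(0L, 0L, 1L, 1L)
  op <- select_threshold(probs, labels, step = 0.01)
  expect_equal(op$macro_f1, 1)
  # all tau in (0.25, 0.80] are perfect; >= comparison makes 0.80 feasible
  # and the tie-break picks the largest such grid point
  expect_equal(op$tau, 0.80)
  expect_error(select_threshold(probs, c(1L, 1L, 1L, 1L)), "both classes")
})

test_that("confusion metrics handle zero denominators safely", {
  m <- classification_metrics(0L, 0L, 2L, 3L)
  expect_equal(m$sensitivity, 0)
  expect_equal(m$f1_pd, 0)
  expect_equal(confusion_at(c(0.5, 0.4), c(1L, 0L), 0.5),
               c(tp = 1L, fn = 0L, fp = 0L, tn = 1L))  # >= at the threshold
})

test_that("roc_auc agrees with pROC and handles ties by midranks", {
  set.seed(5)
  y <- rep(c(0L, 1L), each = 40L)
  p <- stats::runif(80)
  p[y == 1L] <- p[y == 1L] + 0.3
  expect_equal(roc_auc(y, p),
               as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE))))
  # ties: scores all equal give AUC 0.5 exactly
  expect_equal(roc_auc(y, rep(0.7, 80L)), 0.5)
  expect_error(roc_auc(rep(1L, 3L), c(0.1, 0.2, 0.3)), "both classes")
})

test_that("average precision matches the step-integral oracle", {
  y <- c(1L, 0L, 1L, 0L)
  p <- c(0.9, 0.8, 0.7, 0.1)
  # descending: y = 1,0,1,0 -> precision 1, 1/2, 2/3, 2/4 at recall 1/2,.,1,.
  expect_equal(average_precision(y, p), 0.5 * 1 + 0.5 * 2 / 3)
  # grouped ties: both positives tied with one negative
  expect_equal(average_precision(c(1L, 1L, 0L), c(0.6, 0.6, 0.6)), 2 / 3)
})

test_that("Brier and ECE match hand oracles", {
  y <- c(1L, 0L, 1L, 0L)
  p <- c(0.8, 0.3, 0.6, 0.1)
  expect_equal(brier_score(y, p), mean((p - y)^2))
  ec <- expected_calibration_error(y, p, bins = 10L)
  # left-closed bins: 0.8 -> bin 9, 0.3 -> bin 4, 0.6 -> bin 7, 0.1 -> bin 2;
  # each lands alone, so ECE is the mean absolute probability-label gap
  expect_equal(ec$ece, (0.2 + 0.3 + 0.4 + 0.1) / 4)
  expect_equal(sum(ec$table$n), 4L)
  expect_equal(nrow(ec$table), 10L)
  # probabilities 0 and 1 fall into the first and last bin
  ec2 <- expected_calibration_error(c(0L, 1L), c(0, 1), bins = 10L)
  expect_equal(ec2$ece, 0)
})
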