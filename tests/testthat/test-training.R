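test_that("class weights follow w_c = N / (C * N_c)", {
  cw <- class_weights(c("0" = 30L, "1" = 90L))
  expect_equal(unname(cw$w), c(120 / 60, 120 / 180))
  expect_equal(sum(cw$w * cw$counts), cw$N)   # exact rebalancing identity
  expect_error(class_weights(c("0" = 0L, "1" = 5L)), "degenerate")
})

test_that("warm-up/cosine schedule interpolates between its endpoints", {
  sp <- optimizer_spec()
  expect_equal(learning_rate(0, sp), 0)
  expect_equal(learning_rate(2.5, sp), 5e-4 * 2.5 / 5)
  expect_equal(learning_rate(5, sp), 5e-4)
  expect_equal(learning_rate(120, sp), 1e-6)
  expect_error(learning_rate(121, sp), "\\[0, 120\\]")
  expect_error(learning_rate(-1, sp), "\\[0, 120\\]")
  # monotone decline after warm-up
  lrs <- learning_rate(5:120, sp)
  expect_true(all(diff(lrs) < 0))
})

test_that("smoothed early stopping follows the scripted oracle", {
  es <- early_stop_state(smooth_window = 3L, patience = 2L)
  # epoch 1: partial mean 0.6 -> improvement
  es <- early_stop_update(es, 0.6)
  expect_true(es$improved)
  expect_equal(es$best_epoch, 1L)
  # epoch 2: mean(0.6, 0.8) = 0.7 -> improvement
  es <- early_stop_update(es, 0.8)
  expect_equal(es$best_smoothed, 0.7)
  # epoch 3: mean(0.6, 0.8, 0.7) = 0.7, not > best + 1e-6 -> no improvement
  es <- early_stop_update(es, 0.7)
  expect_false(es$improved)
  expect_true(es$continue)
  # epoch 4: mean(0.8, 0.7, 0.6) = 0.7 again -> patience exhausted
  es <- early_stop_update(es, 0.6)
  expect_false(es$continue)
  expect_equal(es$best_epoch, 2L)
})

test_that("multi-seed summary applies the t-interval", {
  s <- summarise_seeds(c(0.90, 0.92, 0.91, 0.89, 0.93))
  expect_equal(s$t_crit, stats::qt(0.975, 4))
  expect_equal(s$ci_high - s$mean, s$t_crit * s$sd / sqrt(5))
  expect_error(summarise_seeds(0.9), "at least two")
  tab <- tibble::tibble(seed = 1:3, auc = c(0.8, 0.9, 1.0),
                        brier = c(0.1, 0.2, 0.3))
  st <- summarise_seeds(tab)
  expect_setequal(st$metric, c("auc", "brier"))  # seed column excluded
  expect_equal(st$mean[st$metric == "auc"], 0.9)
})

test_that("train_senn learns a separable toy problem and restores the best epoch", {
  cfg <- tiny_senn_config()
  train <- toy_problem(n_per_class = 30L, partition = "train", seed = 1L)
  val <- toy_problem(n_per_class = 10L, partition = "val", seed = 2L)
  val$subject_ids <- paste0("v", val$subject_ids)
  m <- train_senn(train, val, cfg, optimizer_spec(t_max = 6L, warmup = 2L,
                                                  batch_size = 16L),
                  seed = 3L)
  expect_s3_class(m, "senn_model")
  expect_true(all(c("epoch", "lr", "loss", "val_auc", "val_auc_subject",
                    "smoothed_auc") %in% names(m$history)))
  expect_gt(max(m$history$val_auc), 0.9)
  expect_equal(m$history$lr, learning_rate(m$history$epoch, m$optimizer))
  # training is a pure function of (data, config, seed)
  m2 <- train_senn(train, val, cfg, optimizer_spec(t_max = 6L, warmup = 2L,
                                                   batch_size = 16L),
                   seed = 3L)
  expect_identical(m$params, m2$params)
  # leakage guard: shared subjects between train and val abort
  expect_error(train_senn(train, train, cfg), "leakage guard")

  ev <- senn_evaluate(m, val)
  ev7 <- senn_evaluate(m, val, chunk = 7L)
  expect_equal(ev$y_hat, ev7$y_hat)            # chunking is invisible
  pr <- predict(m, val)
  expect_s3_class(pr, "tbl_df")
  expect_equal(pr$y_hat, ev$y_hat)

  expect_s3_class(tidy(m), "tbl_df")
  expect_equal(glance(m)$best_epoch, m$best_epoch)
  expect_s3_class(ggplot2::autoplot(m), "ggplot")
})
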