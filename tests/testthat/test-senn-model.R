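test_that("senn_config and the stochastic-depth schedule validate input", {
  expect_error(senn_config(kernel_size = 4L))
  expect_error(senn_config(window = 100L))     # not divisible by 8
  expect_error(senn_config(p_L = 1))
  expect_error(stochastic_depth_schedule(1L, 0.15), "L - 1")
  expect_error(stochastic_depth_schedule(4L, -0.1), "\\[0, 1\\)")
  expect_equal(stochastic_depth_schedule(5L, 0.2), c(0, 0.05, 0.1, 0.15, 0.2))
})

test_that("forward pass shapes, determinism and structural identity", {
  cfg <- tiny_senn_config()
  set.seed(7)
  ini <- senn_init(cfg)
  x <- array(stats::rnorm(6 * 16 * 2), c(6L, 16L, 2L))
  f1 <- senn_forward(ini$params, ini$state, x, cfg)
  f2 <- senn_forward(ini$params, ini$state, x, cfg)
  expect_identical(f1$y_hat, f2$y_hat)          # eval mode is deterministic
  expect_equal(dim(f1$h_tilde), c(6L, 3L))
  expect_equal(dim(f1$theta), c(6L, 3L))
  expect_equal(dim(f1$x_gap), c(6L, 5L))
  expect_equal(f1$z, rowSums(f1$h_tilde * f1$theta))
  expect_true(all(f1$y_hat > 0 & f1$y_hat < 1))
  expect_true(all(abs(f1$h) <= 1))              # tanh-bounded raw concepts
  expect_error(senn_forward(ini$params, ini$state,
                            array(0, c(2L, 8L, 2L)), cfg),
               "do not match")
})

test_that("batch-norm running statistics update only in training mode", {
  cfg <- tiny_senn_config()
  set.seed(8)
  ini <- senn_init(cfg)
  x <- array(stats::rnorm(4 * 16 * 2), c(4L, 16L, 2L))
  ev <- senn_forward(ini$params, ini$state, x, cfg, train = FALSE)
  expect_identical(ev$state, ini$state)
  tr <- senn_forward(ini$params, ini$state, x, cfg, train = TRUE)
  expect_false(identical(tr$state, ini$state))
})

test_that("analytic gradients match central finite differences", {
  cfg <- tiny_senn_config()
  set.seed(42)
  ini <- senn_init(cfg)
  x <- array(stats::rnorm(3 * 16 * 2), c(3L, 16L, 2L))
  y <- c(1L, 0L, 1L)
  w <- c(1, 2, 1.5)
  bk <- senn_backward(ini$params, ini$state, x, y, cfg, weights = w,
                      train = TRUE)
  lossfn <- function(params) {
    fw <- senn_forward(params, ini$state, x, cfg, train = TRUE)
    total_loss(fw, y, cfg, weights = w, params = params)$total
  }
  h <- 1e-5
  for (nm in names(ini$params)) {
    p <- ini$params[[nm]]
    for (i in seq_len(min(length(p), 4L))) {
      pp <- ini$params; pp[[nm]][i] <- pp[[nm]][i] + h
      pm <- ini$params; pm[[nm]][i] <- pm[[nm]][i] - h
      g_fd <- (lossfn(pp) - lossfn(pm)) / (2 * h)
      g_an <- bk$grads[[nm]][i]
      expect_lt(abs(g_fd - g_an) / max(1e-6, abs(g_fd) + abs(g_an)), 1e-4,
                label = sprintf("relative gradient error of %s[%d]", nm, i))
    }
  }
})

test_that("loss components have closed forms and are additive", {
  # label-smoothed BCE against a hand computation
  y <- c(1, 0)
  p <- c(0.9, 0.2)
  ys <- c(0.975, 0.025)
  by_hand <- mean(-(ys * log(p) + (1 - ys) * log(1 - p)))
  expect_equal(smoothed_bce(y, p, 0.05), by_hand)
  # weights are normalised, so rescaling leaves the loss unchanged
  expect_equal(smoothed_bce(y, p, 0.05, weights = c(2, 6)),
               smoothed_bce(y, p, 0.05, weights = c(1, 3)))
  expect_error(smoothed_bce(1, 1.2), "\\[0, 1\\]")

  cfg <- tiny_senn_config()
  set.seed(9)
  ini <- senn_init(cfg)
  x <- array(stats::rnorm(4 * 16 * 2), c(4L, 16L, 2L))
  fw <- senn_forward(ini$params, ini$state, x, cfg)
  lt <- total_loss(fw, c(1, 0, 1, 0), cfg, params = ini$params)
  expect_equal(lt$total, lt$bce + lt$div + lt$spar + lt$stab + lt$l2)
  kn <- grep("conv[12]\\.W$|proj\\.W$", names(ini$params), value = TRUE)
  expect_equal(lt$l2,
               cfg$l2 * sum(vapply(ini$params[kn],
                                   function(w) sum(w^2), 0)))
})

test_that("disabling stochastic depth short-circuits the drop RNG", {
  cfg <- tiny_senn_config()   # p_L = 0
  set.seed(10)
  ini <- senn_init(cfg)
  x <- array(stats::rnorm(2 * 16 * 2), c(2L, 16L, 2L))
  set.seed(77)
  f1 <- senn_forward(ini$params, ini$state, x, cfg, train = TRUE)
  s1 <- .Random.seed
  set.seed(77)
  f2 <- senn_forward(ini$params, ini$state, x, cfg, train = TRUE)
  expect_identical(s1, .Random.seed)
  expect_identical(f1$y_hat, f2$y_hat)
})
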