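test_that("squared-exponential kernel evaluates, is symmetric and bounded", {
  kp <- kernel_params(1, 1, 1)
  a <- tone_stimulus(1000, 40)
  expect_equal(se_kernel(a, a, kp), 1.0)

  # unit lengthscales, coordinate offset (1, 1): exp(-1)
  b <- tone_stimulus(2000, 60)  # +1 octave, +1 scaled level unit
  expect_equal(se_kernel(a, b, kp), exp(-1), tolerance = 1e-12)

  set.seed(42)
  for (i in 1:20) {
    x <- tone_stimulus(runif(1, 125, 8000), runif(1, 10, 80))
    y <- tone_stimulus(runif(1, 125, 8000), runif(1, 10, 80))
    kp2 <- kernel_params(runif(1, 0.5, 8), runif(1, 0.3, 3), runif(1, 0.3, 3))
    expect_identical(se_kernel(x, y, kp2), se_kernel(y, x, kp2))
    expect_lte(se_kernel(x, y, kp2), kp2$signal_variance)
  }

  expect_error(kernel_params(-1, 1, 1), "positive")
  expect_error(kernel_params(1, 0, 1), "positive")
})

test_that("logistic link hits its midpoint, saturates, and is monotone", {
  expect_equal(logistic_link(0), 0.5)
  expect_equal(logistic_link(2), 0.8808, tolerance = 1e-4)
  expect_equal(logistic_link(1e6), 1.0)
  expect_equal(logistic_link(-1e6), 0.0)
  x <- seq(-20, 20, by = 0.5)
  expect_true(all(diff(logistic_link(x)) >= 0))
  # shifted, scaled variant
  lk <- link_params(max_value = 0.9, steepness = 2, midpoint = 1)
  expect_equal(logistic_link(1, lk), 0.45)
})

test_that("Laplace mode of a single trial matches the fixed-point oracle", {
  kp <- kernel_params(1, 1, 1)
  mp <- mean_params(0, 0)
  f1 <- laplace_fit(trial_record(1000, 45, 1), kernel = kp, mean = mp)
  f0 <- laplace_fit(trial_record(1000, 45, 0), kernel = kp, mean = mp)
  expect_equal(f1$f_hat, oracle_mode_1pt(1), tolerance = 1e-6)
  expect_equal(f1$f_hat, 0.4011, tolerance = 1e-3)
  expect_equal(f0$f_hat, -f1$f_hat, tolerance = 1e-9)
  expect_lt(f1$residual, 1e-6)
})

test_that("empty trial set returns the prior", {
  fit <- laplace_fit(NULL)
  grid <- data.frame(frequency_hz = c(250, 1000, 8000),
                     level_db_hl = c(20, 45, 75))
  pr <- predict(fit, grid)
  expect_equal(pr$latent_sd, rep(2, 3))          # sqrt of default variance 4
  expect_equal(pr$latent_mean,
               (grid$level_db_hl - 45) / 20)     # default affine mean
  # at the prior's zero crossing the probability is exactly 1/2
  expect_equal(pr$probability[2], 0.5, tolerance = 1e-12)
  expect_equal(log_marginal_likelihood(fit), 0)
})

test_that("predictive probability reverts to the prior far from data", {
  fit <- laplace_fit(trial_record(250, 20, 1),
                     kernel = kernel_params(1, 1, 1), mean = mean_params(0, 0))
  far <- predict(fit, data.frame(frequency_hz = 8000, level_db_hl = 80))
  expect_equal(far$probability, 0.5, tolerance = 1e-6)
  expect_equal(far$latent_sd, 1, tolerance = 1e-6)
  near <- predict(fit, data.frame(frequency_hz = 250, level_db_hl = 20))
  expect_gt(near$probability, 0.5)
})

test_that("Laplace predictive matches the exact-posterior quadrature oracle", {
  kp <- kernel_params(1, 1, 1)
  mp <- mean_params(0, 0)
  stims <- data.frame(frequency_hz = c(500, 2000), level_db_hl = c(30, 55))
  query <- data.frame(frequency_hz = c(500, 1000, 2000, 8000),
                      level_db_hl = c(30, 45, 55, 75))
  # single point, both labels: tight agreement away from the intrinsic
  # mode-bias scale
  for (y in 0:1) {
    tr <- data.frame(frequency_hz = 500, level_db_hl = 30, response = y)
    lp <- predict(laplace_fit(tr, kernel = kp, mean = mp), query)$probability
    op <- oracle_predictive(tr, query, kernel = kp, mean = mp, grid_pts = 1001)
    expect_lt(max(abs(lp - op)), 3e-3)
  }
  # two points, all label pairs
  for (y1 in 0:1) for (y2 in 0:1) {
    tr <- cbind(stims, response = c(y1, y2))
    lp <- predict(laplace_fit(tr, kernel = kp, mean = mp), query)$probability
    op <- oracle_predictive(tr, query, kernel = kp, mean = mp, grid_pts = 121)
    expect_lt(max(abs(lp - op)), 1e-2)
  }
})

test_that("probabilities stay in [0,1], sd >= 0, and heard labels attract", {
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(1:6, 1)
    tr <- data.frame(
      frequency_hz = runif(n, 125, 8000),
      level_db_hl = runif(n, 10, 80),
      response = sample(0:1, n, replace = TRUE)
    )
    fit <- laplace_fit(tr)
    grid <- data.frame(frequency_hz = runif(15, 125, 8000),
                       level_db_hl = runif(15, 10, 80))
    pr <- predict(fit, grid)
    expect_true(all(pr$probability >= 0 & pr$probability <= 1))
    expect_true(all(pr$latent_sd >= 0))

    # adding a heard label never decreases the probability at that tone
    tone <- data.frame(frequency_hz = runif(1, 125, 8000),
                       level_db_hl = runif(1, 10, 80))
    before <- predict(fit, tone)$probability
    tr2 <- rbind(tr, cbind(tone, response = 1L))
    after <- predict(laplace_fit(tr2), tone)$probability
    expect_gte(after, before - 1e-10)
  }
})

test_that("with positive level slope and no data, audibility is monotone in level", {
  fit <- laplace_fit(NULL, mean = mean_params(0, 1))
  levels <- seq(10, 80, by = 2)
  pr <- predict(fit, data.frame(frequency_hz = 1000, level_db_hl = levels))
  expect_true(all(diff(pr$probability) >= 0))
})

test_that("log marginal likelihood behaves like an evidence", {
  kp <- kernel_params(1, 1, 1)
  mp <- mean_params(0, 0)
  f1 <- laplace_fit(trial_record(1000, 45, 1), kernel = kp, mean = mp)
  # one Bernoulli under a symmetric prior: evidence is exactly 1/2
  expect_lte(log_marginal_likelihood(f1), log(0.5) + 1e-6)
  expect_equal(
    log_marginal_likelihood(f1),
    oracle_evidence(data.frame(frequency_hz = 1000, level_db_hl = 45, response = 1),
                    kernel = kp, mean = mp),
    tolerance = 0.05
  )

  # permutation invariance of the training set
  tr <- data.frame(
    frequency_hz = c(500, 1000, 4000), level_db_hl = c(30, 50, 70),
    response = c(0L, 1L, 1L)
  )
  e1 <- log_marginal_likelihood(laplace_fit(tr))
  e2 <- log_marginal_likelihood(laplace_fit(tr[c(3, 1, 2), ]))
  expect_equal(e1, e2, tolerance = 1e-9)

  # contradictory labels at one location lower the evidence
  agree <- rbind(tr, data.frame(frequency_hz = 1000, level_db_hl = 50, response = 1L))
  contra <- rbind(tr, data.frame(frequency_hz = 1000, level_db_hl = 50, response = 0L))
  expect_lt(log_marginal_likelihood(laplace_fit(contra)),
            log_marginal_likelihood(laplace_fit(agree)))
})

test_that("labels outside {0,1} and bad inputs are rejected", {
  expect_error(trial_record(1000, 40, 2), "labels")
  expect_error(
    laplace_fit(data.frame(frequency_hz = 1000, level_db_hl = 40, response = 0.5)),
    "labels"
  )
  expect_error(tone_stimulus(-100, 40), "positive")
})

test_that("evidence-based kernel selection is deterministic and sane", {
  set.seed(11)
  tr <- data.frame(
    frequency_hz = rep(c(500, 1000, 2000, 4000), each = 2),
    level_db_hl = rep(c(20, 60), 4),
    response = rep(c(0L, 1L), 4)
  )
  cands <- list(kernel_params(4, 1, 1), kernel_params(1, 2, 0.5))
  best1 <- select_kernel_by_evidence(tr, cands)
  best2 <- select_kernel_by_evidence(tr, cands)
  expect_identical(unclass(best1)[1:3], unclass(best2)[1:3])
  expect_length(attr(best1, "evidence"), 2L)
})
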