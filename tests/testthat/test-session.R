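test_that("default seed tones are deterministic, on grid and in range", {
  cfg <- session_config()
  seeds <- default_seed_tones(cfg)
  expect_equal(nrow(seeds), 8L)
  expect_setequal(unique(seeds$frequency_hz), c(500, 1000, 2000, 4000))
  expect_setequal(unique(seeds$level_db_hl), c(30, 60))
  expect_true(all(seeds$level_db_hl >= 10 & seeds$level_db_hl <= 80))
  expect_identical(seeds, default_seed_tones(cfg))

  # narrowed level range clamps the 60-dB seeds to the nearest on-grid level
  cfg2 <- session_config(level_range_db = c(20, 50))
  seeds2 <- default_seed_tones(cfg2)
  expect_setequal(unique(seeds2$level_db_hl), c(30, 50))
  expect_true(all(seeds2$level_db_hl >= 20 & seeds2$level_db_hl <= 50))

  expect_error(session_config(level_range_db = c(0, 80)), "10-80")
  expect_error(session_config(budget_per_ear = 3), "seed tones")
})

test_that("acquisition field is uniform at log 2 under a flat prior", {
  cfg <- session_config(acquisition = "predictive_entropy",
                        mean = mean_params(0, 0))
  field <- acquisition_map(laplace_fit(NULL, mean = mean_params(0, 0)), cfg)
  expect_equal(dim(field$probability),
               c(length(field$freq_hz), length(field$level_db)))
  expect_true(all(abs(field$probability - 0.5) < 1e-12))
  expect_true(all(abs(field$uncertainty - log(2)) < 1e-10))
  expect_true(all(field$uncertainty >= 0))
})

test_that("degenerate probabilities carry zero entropy", {
  expect_equal(audiogp:::bernoulli_entropy(c(0, 1)), c(0, 0))
  expect_equal(audiogp:::bernoulli_entropy(0.5), log(2))
})

test_that("observing a response reduces BALD uncertainty at that cell", {
  cfg <- session_config(acquisition = "bald")
  before <- acquisition_map(laplace_fit(NULL, mean = cfg$mean), cfg)
  i <- which.min(abs(before$freq_hz - 1000))
  j <- which.min(abs(before$level_db - 40))
  tr <- trial_record(before$freq_hz[i], before$level_db[j], 1L)
  after <- acquisition_map(laplace_fit(tr, mean = cfg$mean), cfg)
  expect_lt(after$uncertainty[i, j], before$uncertainty[i, j])
})

test_that("tone selection takes the argmax and breaks ties low-frequency, low-level", {
  cfg <- session_config()
  ax_field <- acquisition_map(laplace_fit(NULL, mean = mean_params(0, 0)),
                              session_config(mean = mean_params(0, 0)))
  # constant field: tie-break to lowest frequency, lowest level
  ax_field$uncertainty[] <- 1
  t1 <- select_next_tone(ax_field, cfg)
  expect_equal(t1$frequency_hz, min(ax_field$freq_hz))
  expect_equal(t1$level_db_hl, min(ax_field$level_db))

  # unique maximum
  ax_field$uncertainty[5, 7] <- 2
  t2 <- select_next_tone(ax_field, cfg)
  expect_equal(t2$frequency_hz, ax_field$freq_hz[5])
  expect_equal(t2$level_db_hl, ax_field$level_db[7])

  # two equal maxima at the same frequency: lower level wins
  ax_field$uncertainty[] <- 1
  ax_field$uncertainty[5, c(7, 12)] <- 2
  t3 <- select_next_tone(ax_field, cfg)
  expect_equal(t3$level_db_hl, ax_field$level_db[7])
})

test_that("updating one ear leaves the other untouched and counts trials", {
  state <- new_session(session_config())
  right_before <- state$posterior$right
  state <- update_session(state, trial_record(1000, 40, 1, "left"))
  expect_equal(nrow(state$trials$left), 1L)
  expect_equal(nrow(state$trials$right), 0L)
  expect_identical(state$posterior$right, right_before)
  expect_equal(state$next_ear, "right")
  expect_error(update_session(state, trial_record(1000, 40, 2, "left")),
               "labels")
  expect_error(update_session(state, trial_record(1000, 5, 1, "left")),
               "dynamic range")
})

test_that("per-ear refits depend only on that ear's trials, not interleaving", {
  cfg <- session_config()
  trs <- list(
    trial_record(500, 30, 0, "left"), trial_record(500, 35, 1, "right"),
    trial_record(1000, 50, 1, "left"), trial_record(4000, 60, 1, "right"),
    trial_record(2000, 20, 0, "left")
  )
  s1 <- new_session(cfg)
  for (tr in trs) s1 <- update_session(s1, tr)
  # replay left-ear trials alone
  s2 <- new_session(cfg)
  for (tr in trs) if (tr$ear == "left") s2 <- update_session(s2, tr)
  expect_equal(s1$posterior$left$f_hat, s2$posterior$left$f_hat)
})

test_that("stopping honours the budget and the early-stop tolerance", {
  cfg <- session_config(budget_per_ear = 10)
  state <- new_session(cfg)
  expect_equal(should_stop(state, cfg), c(left = FALSE, right = FALSE))
  for (i in 1:10) {
    state <- update_session(state, trial_record(1000, 20 + 2 * i, 1, "left"))
  }
  expect_equal(should_stop(state, cfg), c(left = TRUE, right = FALSE))

  cfg2 <- session_config(budget_per_ear = 10, early_stop_tol = 1e9)
  state2 <- new_session(cfg2)
  state2 <- update_session(state2, trial_record(1000, 40, 1, "left"))
  stops <- should_stop(state2, cfg2)
  expect_true(stops["left"])    # any positive tolerance that large fires at once
  expect_false(stops["right"])  # no data yet on the right
})

test_that("threshold extraction finds the 0.5 boundary of a trained posterior", {
  # near-deterministic listener around 40 dB: dense noiseless labels
  levels <- seq(10, 80, by = 4)
  freqs <- c(250, 500, 1000, 2000, 4000, 8000)
  tr <- expand.grid(frequency_hz = freqs, level_db_hl = levels)
  tr$response <- as.integer(tr$level_db_hl >= 40)
  fit <- laplace_fit(tr)
  curve <- extract_threshold(fit, session_config())
  expect_s3_class(curve, "threshold_curve")
  expect_true(all(curve$valid))
  expect_lt(max(abs(curve$threshold_db_hl - 40)), 4)
  expect_true(all(curve$band_low_db <= curve$threshold_db_hl + 1e-9))
  expect_true(all(curve$threshold_db_hl <= curve$band_high_db + 1e-9))
  expect_true(all(curve$threshold_db_hl >= 10 & curve$threshold_db_hl <= 80))
})

test_that("sessions with ceiling/floor listeners pin the curve and flag invalid", {
  cfg <- session_config(random_seed = 3)
  always <- run_session(function(tone, ear) 1L, cfg, ears = "left")
  expect_true(all(!always$curves$left$valid))
  expect_true(all(always$curves$left$threshold_db_hl == 10))

  never <- run_session(function(tone, ear) 0L, cfg, ears = "left")
  expect_true(all(!never$curves$left$valid))
  expect_true(all(never$curves$left$threshold_db_hl == 80))
})

test_that("a full session is budget-bound, in-range, on-grid and reproducible", {
  cfg <- session_config(random_seed = 7, budget_per_ear = 20)
  listener1 <- make_phenotype("flat_mild", rng_seed = 7)
  listener2 <- make_phenotype("flat_mild", rng_seed = 7)
  r1 <- run_session(make_responder(listener1), cfg)
  r2 <- run_session(make_responder(listener2), cfg)
  for (ear in c("left", "right")) {
    tr <- r1$state$trials[[ear]]
    expect_equal(nrow(tr), 20L)
    expect_true(all(tr$level_db_hl >= 10 & tr$level_db_hl <= 80))
    expect_true(all(tr$frequency_hz >= 125 & tr$frequency_hz <= 8000))
    # on-grid: levels multiples of 2, frequencies on the 1/6-octave lattice
    expect_true(all(tr$level_db_hl %% 2 == 0))
    octs <- log2(tr$frequency_hz / 125) * 6
    expect_true(all(abs(octs - round(octs)) < 1e-9))
    expect_identical(r1$state$trials[[ear]], r2$state$trials[[ear]])
    expect_equal(r1$curves[[ear]], r2$curves[[ear]])
  }
})

test_that("a failing responder aborts but preserves partial state", {
  n_calls <- 0
  flaky <- function(tone, ear) {
    n_calls <<- n_calls + 1
    if (n_calls > 5) stop("button jammed")
    1L
  }
  err <- tryCatch(run_session(flaky, session_config(random_seed = 1), ears = "left"),
                  audiogp_session_error = function(e) e)
  expect_s3_class(err, "audiogp_session_error")
  expect_equal(nrow(err$state$trials$left), 5L)
})

test_that("flat-35 listener is recovered within 5 dB mean absolute error", {
  listener <- make_phenotype("flat_mild", rng_seed = 0)
  res <- run_session(make_responder(listener),
                     session_config(random_seed = 0), ears = "left")
  est <- resample_m2_at_standard(res$curves$left, comparison_frequencies())
  expect_lte(mean(abs(est - 35)), 5)
})
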