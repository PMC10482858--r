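#' Session configuration
#'
#' Configuration of the active audiometry loop: tone-space extent and grid,
#' seed tones, response budget, acquisition rule and stopping. The defaults
#' are the study conditions: levels confined to 10-80 dB HL (the output
#' range of the test device), frequencies 125-8000 Hz, and a budget of 35
#' responses per ear (seed tones count toward the budget).
#'
#' @param freq_range_hz frequency extent, Hz (pair).
#' @param level_range_db level extent, dB HL (pair); must lie within
#'   `[10, 80]`.
#' @param grid_freq_step_oct frequency grid step in octaves (default 1/6).
#' @param grid_level_step_db level grid step in dB (default 2).
#' @param seed_tones data.frame of seed tones (`frequency_hz`,
#'   `level_db_hl`), used for both ears; `NULL` for the default list
#'   ([default_seed_tones()]).
#' @param budget_per_ear total responses collected per ear, seeds included.
#' @param early_stop_tol stop an ear early once the maximum acquisition
#'   value drops below this; 0 disables (the default: a fixed budget, as in
#'   the study).
#' @param acquisition `"bald"` (mutual information between response and
#'   latent; the default), `"predictive_entropy"`, or `"latent_variance"`.
#' @param random_seed integer seed applied at the start of [run_session()].
#' @param kernel,mean,link,level_scale GP configuration, see [laplace_fit()].
#' @return a validated list of class `"session_config"`.
#' @export
session_config <- function(freq_range_hz = c(125, 8000),
                           level_range_db = c(10, 80),
                           grid_freq_step_oct = 1 / 6,
                           grid_level_step_db = 2,
                           seed_tones = NULL,
                           budget_per_ear = 35,
                           early_stop_tol = 0,
                           acquisition = c("bald", "predictive_entropy", "latent_variance"),
                           random_seed = 1L,
                           kernel = kernel_params(),
                           mean = mean_params(),
                           link = link_params(),
                           level_scale = 20) {
  acquisition <- match.arg(acquisition)
  stopifnot(
    length(freq_range_hz) == 2, freq_range_hz[1] > 0,
    freq_range_hz[1] < freq_range_hz[2],
    length(level_range_db) == 2, level_range_db[1] < level_range_db[2],
    grid_freq_step_oct > 0, grid_level_step_db > 0,
    budget_per_ear >= 1, early_stop_tol >= 0
  )
  if (level_range_db[1] < 10 || level_range_db[2] > 80) {
    stop("`level_range_db` must lie within the 10-80 dB HL device range",
         call. = FALSE)
  }
  cfg <- structure(
    list(
      freq_range_hz = as.numeric(freq_range_hz),
      level_range_db = as.numeric(level_range_db),
      grid_freq_step_oct = grid_freq_step_oct,
      grid_level_step_db = grid_level_step_db,
      seed_tones = seed_tones,
      budget_per_ear = as.integer(budget_per_ear),
      early_stop_tol = early_stop_tol,
      acquisition = acquisition,
      random_seed = as.integer(random_seed),
      kernel = kernel, mean = mean, link = link,
      level_scale = level_scale
    ),
    class = "session_config"
  )
  if (is.null(cfg$seed_tones)) cfg$seed_tones <- default_seed_tones(cfg)
  if (nrow(cfg$seed_tones) > cfg$budget_per_ear) {
    stop("`budget_per_ear` must be at least the number of seed tones",
         call. = FALSE)
  }
  bad <- cfg$seed_tones$level_db_hl < level_range_db[1] |
    cfg$seed_tones$level_db_hl > level_range_db[2] |
    cfg$seed_tones$frequency_hz < freq_range_hz[1] |
    cfg$seed_tones$frequency_hz > freq_range_hz[2]
  if (any(bad)) {
    stop("seed tones fall outside the configured tone space", call. = FALSE)
  }
  cfg
}

# tone-space grid axes of a config
grid_axes <- function(config) {
  octs <- seq(0, log2(config$freq_range_hz[2] / config$freq_range_hz[1]),
              by = config$grid_freq_step_oct)
  freq <- config$freq_range_hz[1] * 2^octs
  level <- seq(config$level_range_db[1], config$level_range_db[2],
               by = config$grid_level_step_db)
  list(freq = freq, level = level)
}

#' Default seed tones
#'
#' The pre-specified tones played before active selection starts: 500, 1000,
#' 2000 and 4000 Hz, each at 30 and 60 dB HL (8 seeds per ear), chosen to
#' straddle typical hearing thresholds. Seeds are snapped to the nearest
#' on-grid, in-range cell of the configured tone space, so a narrowed level
#' range clamps them rather than failing.
#'
#' @param config a [session_config()]; `NULL` for the defaults.
#' @return data.frame with columns `frequency_hz`, `level_db_hl`.
#' @export
default_seed_tones <- function(config = NULL) {
  freqs <- c(500, 1000, 2000, 4000)
  levels <- c(30, 60)
  seeds <- expand.grid(frequency_hz = freqs, level_db_hl = levels,
                       KEEP.OUT.ATTRS = FALSE)
  seeds <- seeds[order(seeds$frequency_hz, seeds$level_db_hl), , drop = FALSE]
  rownames(seeds) <- NULL
  if (is.null(config)) return(seeds)
  ax <- grid_axes(config)
  seeds$frequency_hz <- vapply(seeds$frequency_hz, function(f) {
    ax$freq[which.min(abs(log2(ax$freq) - log2(f)))]
  }, numeric(1))
  seeds$level_db_hl <- vapply(seeds$level_db_hl, function(l) {
    ax$level[which.min(abs(ax$level - l))]
  }, numeric(1))
  seeds
}

#' Session state
#'
#' Mutable-by-replacement record of a two-ear testing session: per-ear trial
#' lists, fitted posteriors, the last computed acquisition field, and whose
#' turn is next. Ears are statistically independent: updating one never
#' touches the other's posterior.
#'
#' @param config a [session_config()].
#' @return an object of class `"session_state"`.
#' @export
new_session <- function(config = session_config()) {
  empty_fit <- laplace_fit(
    empty_trials(), kernel = config$kernel, mean = config$mean,
    link = config$link, level_scale = config$level_scale
  )
  structure(
    list(
      config = config,
      trials = list(left = empty_trials(), right = empty_trials()),
      posterior = list(left = empty_fit, right = empty_fit),
      field = list(left = NULL, right = NULL),
      next_ear = "left"
    ),
    class = "session_state"
  )
}

#' @export
print.session_state <- function(x, ...) {
  cat(sprintf(
    "audiometry session: %d left / %d right trials (budget %d per ear)\n",
    nrow(x$trials$left), nrow(x$trials$right), x$config$budget_per_ear
  ))
  invisible(x)
}

bernoulli_entropy <- function(p) {
  h <- numeric(length(p))
  ok <- p > 0 & p < 1
  h[ok] <- -(p[ok] * log(p[ok]) + (1 - p[ok]) * log1p(-p[ok]))
  h
}

#' Posterior and acquisition field over the tone grid
#'
#' Evaluates the predictive audibility probability on the full tone grid and
#' scores every cell with the configured acquisition rule:
#' * `predictive_entropy` — Bernoulli entropy of the predictive probability;
#' * `bald` — mutual information between the response and the latent
#'   function (predictive entropy minus the expected entropy of the
#'   conditional response, the expectation taken by Gauss-Hermite
#'   quadrature over the latent Gaussian). High only where uncertainty is
#'   reducible, so irreducibly noisy regions are not re-queried;
#' * `latent_variance` — the latent predictive variance.
#'
#' @param posterior a `"gp_posterior"` for one ear.
#' @param config a [session_config()].
#' @return object of class `"posterior_field"`: list with `freq_hz`,
#'   `level_db`, and matrices `probability`, `uncertainty`, `latent_mean`,
#'   `latent_sd` (frequencies in rows, levels in columns).
#' @export
acquisition_map <- function(posterior, config = session_config()) {
  ax <- grid_axes(config)
  grid <- expand.grid(frequency_hz = ax$freq, level_db_hl = ax$level,
                      KEEP.OUT.ATTRS = FALSE)
  pr <- predict(posterior, grid)
  p <- pr$probability
  unc <- switch(config$acquisition,
    predictive_entropy = bernoulli_entropy(p),
    latent_variance = pr$latent_sd^2,
    bald = {
      gh <- gauss_hermite_rule(32)
      z <- outer(pr$latent_sd * sqrt(2), gh$x) + pr$latent_mean
      cond_h <- bernoulli_entropy(logistic_link(z, posterior$link))
      pmax(bernoulli_entropy(p) -
             as.numeric(matrix(cond_h, nrow(z)) %*% gh$w) / sqrt(pi), 0)
    }
  )
  nf <- length(ax$freq)
  structure(
    list(
      freq_hz = ax$freq, level_db = ax$level,
      probability = matrix(p, nf),
      uncertainty = matrix(pmax(unc, 0), nf),
      latent_mean = matrix(pr$latent_mean, nf),
      latent_sd = matrix(pr$latent_sd, nf)
    ),
    class = "posterior_field"
  )
}

#' @export
print.posterior_field <- function(x, ...) {
  cat(sprintf(
    "posterior field: %d freqs x %d levels; max acquisition %.4g\n",
    length(x$freq_hz), length(x$level_db), max(x$uncertainty)
  ))
  invisible(x)
}

#' Select the next tone to play
#'
#' Argmax of the acquisition field; exact ties are broken toward lower
#' frequency, then lower level, so the selection is deterministic.
#'
#' @param field a `"posterior_field"` from [acquisition_map()].
#' @param config a [session_config()].
#' @return a [tone_stimulus()] on the grid and inside the level range.
#' @export
select_next_tone <- function(field, config = session_config()) {
  if (!length(field$uncertainty)) stop("empty acquisition field", call. = FALSE)
  u <- field$uncertainty
  best <- which(u == max(u), arr.ind = TRUE)
  # order candidates by (frequency, level); rows index frequency
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
  tone_stimulus(field$freq_hz[best[1, 1]], field$level_db[best[1, 2]],
                config$level_scale)
}

#' Record a trial and refit
#'
#' Appends the trial to its ear's record, refits that ear's posterior, and
#' passes the turn to the other ear. The untouched ear's posterior is
#' returned bit-identical.
#'
#' @param state a `"session_state"`.
#' @param trial one-row trial data.frame ([trial_record()]).
#' @return the updated `"session_state"`.
#' @export
update_session <- function(state, trial) {
  stopifnot(inherits(state, "session_state"), nrow(trial) == 1L)
  check_labels(trial$response)
  ear <- match.arg(trial$ear, c("left", "right"))
  cfg <- state$config
  if (trial$level_db_hl < cfg$level_range_db[1] ||
      trial$level_db_hl > cfg$level_range_db[2]) {
    stop("trial level outside the configured dynamic range", call. = FALSE)
  }
  if (nrow(state$trials[[ear]]) >= cfg$budget_per_ear) {
    stop("response budget for this ear is exhausted", call. = FALSE)
  }
  state$trials[[ear]] <- rbind(state$trials[[ear]], as.data.frame(trial))
  state$posterior[[ear]] <- laplace_fit(
    state$trials[[ear]], kernel = cfg$kernel, mean = cfg$mean,
    link = cfg$link, level_scale = cfg$level_scale
  )
  state$next_ear <- setdiff(c("left", "right"), ear)
  state
}

#' Stopping rule
#'
#' An ear stops once its response budget is spent, or — when an early-stop
#' tolerance is configured — once the maximum acquisition value over the
#' grid has dropped below that tolerance (additional tones would only
#' provide marginal new information).
#'
#' @param state a `"session_state"`.
#' @param config a [session_config()]; defaults to the state's own.
#' @return named logical vector `c(left = , right = )`.
#' @export
should_stop <- function(state, config = state$config) {
  vapply(c(left = "left", right = "right"), function(ear) {
    n <- nrow(state$trials[[ear]])
    if (n >= config$budget_per_ear) return(TRUE)
    if (config$early_stop_tol > 0 && n > 0) {
      field <- state$field[[ear]]
      if (is.null(field)) field <- acquisition_map(state$posterior[[ear]], config)
      return(max(field$uncertainty) < config$early_stop_tol)
    }
    FALSE
  }, logical(1))
}

#' Extract the threshold curve
#'
#' The decision boundary of the classifier, read per grid frequency as the
#' lowest level at which the audibility probability reaches 0.5 (linear
#' interpolation between the bracketing grid levels). The credible band
#' comes from the levels where the latent mean -/+ 1.96 latent sd crosses
#' zero (the link expectation equals 0.5 exactly where the latent mean is
#' zero, so boundary and band are on the same scale). Frequencies whose
#' crossing falls outside the dynamic range are flagged invalid with the
#' threshold pinned to the nearer range edge.
#'
#' @param posterior a `"gp_posterior"` for one ear.
#' @param config a [session_config()].
#' @return object of class `"threshold_curve"`: data.frame with columns
#'   `frequency_hz`, `threshold_db_hl`, `band_low_db`, `band_high_db`,
#'   `valid`.
#' @export
extract_threshold <- function(posterior, config = session_config()) {
  field <- acquisition_map(posterior, config)
  lo <- config$level_range_db[1]
  hi <- config$level_range_db[2]

  cross_up <- function(values, levels) {
    # lowest level where `values` crosses 0 from below, linear interpolation
    idx <- which(values >= 0)
    if (!length(idx)) return(c(NA_real_, FALSE))
    i <- idx[1]
    if (i == 1L) return(c(NA_real_, FALSE))
    l <- levels[i - 1] + (0 - values[i - 1]) /
      (values[i] - values[i - 1]) * (levels[i] - levels[i - 1])
    c(l, TRUE)
  }

  nf <- length(field$freq_hz)
  threshold <- band_lo <- band_hi <- numeric(nf)
  valid <- logical(nf)
  for (i in seq_len(nf)) {
    mlat <- field$latent_mean[i, ]
    slat <- field$latent_sd[i, ]
    th <- cross_up(mlat, field$level_db)
    if (th[2] == 1) {
      threshold[i] <- th[1]
      valid[i] <- TRUE
      optimistic <- cross_up(mlat + 1.96 * slat, field$level_db)
      pessimistic <- cross_up(mlat - 1.96 * slat, field$level_db)
      band_lo[i] <- if (optimistic[2] == 1) optimistic[1] else lo
      band_hi[i] <- if (pessimistic[2] == 1) pessimistic[1] else hi
      band_lo[i] <- min(band_lo[i], threshold[i])
      band_hi[i] <- max(band_hi[i], threshold[i])
    } else {
      # no in-range crossing: pin to the nearer edge
      threshold[i] <- if (mlat[1] >= 0) lo else hi
      band_lo[i] <- lo
      band_hi[i] <- hi
      valid[i] <- FALSE
    }
  }
  structure(
    data.frame(
      frequency_hz = field$freq_hz,
      threshold_db_hl = threshold,
      band_low_db = band_lo,
      band_high_db = band_hi,
      valid = valid
    ),
    class = c("threshold_curve", "data.frame")
  )
}

#' Run a full active audiometry session
#'
#' Plays the seed tones, then iterates per ear — refit, score the grid with
#' the acquisition rule, play the most informative tone, record the answer —
#' strictly alternating ears until each ear's stopping rule fires. Fully
#' reproducible given `config$random_seed` and a deterministic responder.
#'
#' @param responder function `(tone, ear) -> 0/1`; e.g. [make_responder()]
#'   wrapping a simulated listener, or a closure around live user input.
#' @param config a [session_config()].
#' @param ears ears to test (default both).
#' @return list with `state` (the final `"session_state"`) and `curves`
#'   (named list of `"threshold_curve"` per tested ear). If the responder
#'   throws, the session aborts with an error of class
#'   `"audiogp_session_error"` carrying the partial state in
#'   `condition$state`.
#' @examples
#' listener <- make_phenotype("flat_mild", rng_seed = 1)
#' res <- run_session(make_responder(listener),
#'                    session_config(random_seed = 1), ears = "left")
#' res$curves$left[1:5, ]
#' @export
run_session <- function(responder, config = session_config(),
                        ears = c("left", "right")) {
  ears <- match.arg(ears, c("left", "right"), several.ok = TRUE)
  state <- new_session(config)
  set.seed(config$random_seed)

  ask <- function(tone, ear) {
    r <- tryCatch(responder(tone, ear), error = function(e) e)
    if (inherits(r, "error")) {
      cond <- structure(
        class = c("audiogp_session_error", "error", "condition"),
        list(
          message = paste0("responder failed: ", conditionMessage(r)),
          call = sys.call(-1), state = state
        )
      )
      stop(cond)
    }
    r
  }

  for (ear in ears) {
    for (i in seq_len(nrow(config$seed_tones))) {
      tone <- tone_stimulus(config$seed_tones$frequency_hz[i],
                            config$seed_tones$level_db_hl[i],
                            config$level_scale)
      resp <- ask(tone, ear)
      state <- update_session(state, trial_record(
        tone$frequency_hz, tone$level_db_hl, resp, ear
      ))
    }
  }

  repeat {
    stopped <- should_stop(state, config)
    active <- ears[!stopped[ears]]
    if (!length(active)) break
    ear <- if (state$next_ear %in% active) state$next_ear else active[1]
    field <- acquisition_map(state$posterior[[ear]], config)
    state$field[[ear]] <- field
    tone <- select_next_tone(field, config)
    resp <- ask(tone, ear)
    state <- update_session(state, trial_record(
      tone$frequency_hz, tone$level_db_hl, resp, ear
    ))
  }

  curves <- lapply(stats::setNames(ears, ears), function(ear) {
    extract_threshold(state$posterior[[ear]], config)
  })
  list(state = state, curves = curves)
}
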