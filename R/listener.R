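#' Simulated listeners
#'
#' A listener is defined by a true threshold curve per ear (a lookup table
#' over frequency, interpolated log-linearly in frequency), a logistic
#' psychometric function in level, and guess/lapse rates:
#' `P(heard) = guess + (1 - guess - lapse) * plogis(slope * (level - threshold(f)))`.
#' Responses are Bernoulli draws from a private, seeded random stream, so a
#' listener's answer sequence is reproducible regardless of the caller's RNG
#' use.
#'
#' @param true_threshold data.frame with columns `frequency_hz`,
#'   `threshold_db_hl` (used for both ears), or a named list
#'   `list(left = , right = )` of such tables.
#' @param psychometric_slope logistic slope in probability per dB; `Inf`
#'   gives the noiseless step observer (hears iff the level reaches the
#'   true threshold).
#' @param guess_rate lower asymptote (false alarms), in `[0, 0.5)`.
#' @param lapse_rate upper-asymptote deficit (inattention), in `[0, 0.5)`.
#' @param rng_seed integer seed of the listener's private response stream.
#' @return an object of class `"listener_profile"`.
#' @export
listener_profile <- function(true_threshold,
                             psychometric_slope = 1,
                             guess_rate = 0.02,
                             lapse_rate = 0.02,
                             rng_seed = 1L) {
  stopifnot(psychometric_slope > 0,
            guess_rate >= 0, guess_rate < 0.5,
            lapse_rate >= 0, lapse_rate < 0.5)
  if (is.data.frame(true_threshold)) {
    true_threshold <- list(left = true_threshold, right = true_threshold)
  }
  for (ear in c("left", "right")) {
    tt <- true_threshold[[ear]]
    stopifnot(is.data.frame(tt),
              all(c("frequency_hz", "threshold_db_hl") %in% names(tt)),
              all(tt$frequency_hz > 0))
  }
  rng <- new.env(parent = emptyenv())
  rng$state <- NULL
  structure(
    list(
      true_threshold = true_threshold,
      psychometric_slope = psychometric_slope,
      guess_rate = guess_rate,
      lapse_rate = lapse_rate,
      rng_seed = as.integer(rng_seed),
      .rng = rng
    ),
    class = "listener_profile"
  )
}

#' @export
print.listener_profile <- function(x, ...) {
  rng <- range(x$true_threshold$left$threshold_db_hl)
  cat(sprintf(
    "simulated listener: thresholds %.4g-%.4g dB HL, slope %.3g/dB, guess %.3g, lapse %.3g, seed %d\n",
    rng[1], rng[2], x$psychometric_slope, x$guess_rate, x$lapse_rate, x$rng_seed
  ))
  invisible(x)
}

#' True threshold of a simulated listener at arbitrary frequencies
#'
#' Log-linear interpolation of the listener's threshold table; constant
#' extrapolation beyond the tabled frequencies.
#'
#' @param profile a [listener_profile()].
#' @param frequency_hz frequencies to evaluate, Hz.
#' @param ear `"left"` or `"right"`.
#' @return thresholds in dB HL.
#' @export
true_threshold_at <- function(profile, frequency_hz, ear = "left") {
  tt <- profile$true_threshold[[match.arg(ear, c("left", "right"))]]
  stats::approx(log2(tt$frequency_hz), tt$threshold_db_hl,
                xout = log2(frequency_hz), rule = 2)$y
}

#' Canonical listener phenotypes
#'
#' Deterministic ground-truth audiograms used throughout the recovery
#' property suite:
#' * `normal` — flat 10 dB HL;
#' * `flat_mild` — flat 35 dB HL;
#' * `flat_moderate` — flat 50 dB HL;
#' * `sloping_hf` — 10 dB HL up to 1 kHz, rising log-linearly (in octaves)
#'   to 60 dB HL at 8 kHz, the classic sloping high-frequency loss.
#'
#' All use psychometric slope 1 per dB and guess = lapse = 0.02 unless
#' overridden.
#'
#' @param name phenotype name.
#' @param rng_seed seed of the listener's private response stream.
#' @param ... overrides passed on to [listener_profile()].
#' @return a [listener_profile()].
#' @export
make_phenotype <- function(name = c("normal", "flat_mild", "flat_moderate", "sloping_hf"),
                           rng_seed = 1L, ...) {
  name <- match.arg(name)
  freqs <- c(125, 250, 500, 750, 1000, 1500, 2000, 3000, 4000, 6000, 8000)
  thr <- switch(name,
    normal = rep(10, length(freqs)),
    flat_mild = rep(35, length(freqs)),
    flat_moderate = rep(50, length(freqs)),
    sloping_hf = ifelse(freqs <= 1000, 10,
                        10 + 50 * log2(freqs / 1000) / log2(8))
  )
  listener_profile(
    data.frame(frequency_hz = freqs, threshold_db_hl = thr),
    rng_seed = rng_seed, ...
  )
}

# draw uniforms from the profile's private stream without disturbing the
# caller's RNG state
private_runif <- function(profile, n = 1L) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  if (is.null(profile$.rng$state)) {
    set.seed(profile$rng_seed)
  } else {
    assign(".Random.seed", profile$.rng$state, envir = globalenv())
  }
  u <- stats::runif(n)
  profile$.rng$state <- get(".Random.seed", globalenv())
  u
}

#' Probability that a listener hears a tone
#'
#' @param profile a [listener_profile()].
#' @param frequency_hz,level_db_hl the tone.
#' @param ear `"left"` or `"right"`.
#' @return detection probability, in `[guess, 1 - lapse]`.
#' @export
response_probability <- function(profile, frequency_hz, level_db_hl, ear = "left") {
  thr <- true_threshold_at(profile, frequency_hz, ear)
  core <- if (is.infinite(profile$psychometric_slope)) {
    # noiseless step observer: hears iff the level reaches the threshold
    as.numeric(level_db_hl >= thr)
  } else {
    stats::plogis(profile$psychometric_slope * (level_db_hl - thr))
  }
  profile$guess_rate + (1 - profile$guess_rate - profile$lapse_rate) * core
}

#' Simulated response to a tone
#'
#' Bernoulli draw from the listener's psychometric function, using the
#' listener's private seeded stream (deterministic given `rng_seed` and the
#' call sequence).
#'
#' @param profile a [listener_profile()].
#' @param tone a [tone_stimulus()].
#' @param ear `"left"` or `"right"`.
#' @return 1 (heard) or 0 (not heard).
#' @export
respond <- function(profile, tone, ear = "left") {
  p <- response_probability(profile, tone$frequency_hz, tone$level_db_hl, ear)
  as.integer(private_runif(profile) < p)
}

#' @rdname respond
#' @return `make_responder()` returns a function `(tone, ear) -> 0/1`
#'   suitable as the responder callback of [run_session()].
#' @export
make_responder <- function(profile) {
  function(tone, ear) respond(profile, tone, ear)
}

#' Modified Hughson-Westlake staircase at one frequency
#'
#' The clinical "up 5 dB - down 10 dB" threshold search: descend 10 dB
#' after each heard tone, ascend 5 dB after each miss. The threshold is the
#' lowest level heard on at least 2 of up to 3 ascending passes. The start
#' level is snapped to the 5-dB grid, so every emitted level is a multiple
#' of 5 and consecutive presentations differ by exactly -10 or +5 dB.
#' A listener who never responds in range returns the range ceiling
#' (flagged `"ceiling"`); one who always responds returns the floor
#' (flagged `"floor"`).
#'
#' @param profile a [listener_profile()].
#' @param frequency_hz test frequency, Hz.
#' @param start_level_db first presentation level, dB HL.
#' @param range_db level range searched (standard audiometers reach below
#'   the 10 dB HL device floor of the in-situ method, so the default floor
#'   is -10 dB HL).
#' @param ear `"left"` or `"right"`.
#' @param max_presentations safety cap on the number of tones.
#' @return list with `threshold_db_hl`, `flag` (`"ok"`, `"floor"`,
#'   `"ceiling"`, `"no_convergence"`), `n_trials` and the presentation log
#'   (`level_db_hl`, `response`).
#' @export
hughson_westlake <- function(profile, frequency_hz, start_level_db = 40,
                             range_db = c(-10, 100), ear = "left",
                             max_presentations = 200L) {
  stopifnot(length(range_db) == 2, range_db[1] < range_db[2])
  floor_db <- 5 * ceiling(range_db[1] / 5)
  ceil_db <- 5 * floor(range_db[2] / 5)
  level <- 5 * round(start_level_db / 5)
  level <- min(max(level, floor_db), ceil_db)

  levels_log <- integer(0)
  resp_log <- integer(0)
  asc_hits <- list()    # per level: c(hits, visits) on ascending passes
  ascending <- FALSE
  floor_hits <- 0L
  ceiling_misses <- 0L
  result <- NULL

  for (i in seq_len(max_presentations)) {
    tone <- tone_stimulus(frequency_hz, level)
    r <- respond(profile, tone, ear)
    levels_log <- c(levels_log, level)
    resp_log <- c(resp_log, r)
    key <- as.character(level)
    if (r == 1L) {
      if (ascending) {
        cur <- asc_hits[[key]] %||% c(0L, 0L)
        asc_hits[[key]] <- cur + c(1L, 1L)
        if (asc_hits[[key]][1] >= 2L) {
          result <- list(threshold_db_hl = level, flag = "ok")
          break
        }
      }
      if (level <= floor_db) {
        floor_hits <- floor_hits + 1L
        if (floor_hits >= 2L) {
          result <- list(threshold_db_hl = floor_db, flag = "floor")
          break
        }
      }
      level <- max(level - 10, floor_db)
      ascending <- FALSE
    } else {
      if (ascending) {
        cur <- asc_hits[[key]] %||% c(0L, 0L)
        asc_hits[[key]] <- cur + c(0L, 1L)
      }
      if (level >= ceil_db) {
        ceiling_misses <- ceiling_misses + 1L
        if (ceiling_misses >= 2L) {
          result <- list(threshold_db_hl = ceil_db, flag = "ceiling")
          break
        }
      }
      level <- min(level + 5, ceil_db)
      ascending <- TRUE
    }
  }
  if (is.null(result)) {
    result <- list(threshold_db_hl = level, flag = "no_convergence")
  }
  result$n_trials <- length(levels_log)
  result$log <- data.frame(level_db_hl = levels_log, response = resp_log)
  result
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Standard staircase audiogram at the 11 audiometric frequencies
#'
#' Runs [hughson_westlake()] at 125, 250, 500, 750, 1000, 1500, 2000, 3000,
#' 4000, 6000 and 8000 Hz for each requested ear.
#'
#' @param profile a [listener_profile()].
#' @param ears ears to test.
#' @inheritParams hughson_westlake
#' @return object of class `"staircase_result"`: data.frame with columns
#'   `frequency_hz`, `ear`, `threshold_db_hl`, `flag`, `n_trials`.
#' @export
standard_audiogram <- function(profile, ears = c("left", "right"),
                               start_level_db = 40, range_db = c(-10, 100)) {
  ears <- match.arg(ears, c("left", "right"), several.ok = TRUE)
  freqs <- c(125, 250, 500, 750, 1000, 1500, 2000, 3000, 4000, 6000, 8000)
  rows <- list()
  for (ear in ears) {
    for (f in freqs) {
      hw <- hughson_westlake(profile, f, start_level_db, range_db, ear)
      rows[[length(rows) + 1L]] <- data.frame(
        frequency_hz = f, ear = ear,
        threshold_db_hl = hw$threshold_db_hl,
        flag = hw$flag, n_trials = hw$n_trials,
        stringsAsFactors = FALSE
      )
    }
  }
  structure(do.call(rbind, rows),
            class = c("staircase_result", "data.frame"))
}

#' Read/write audiogram tables as CSV
#'
#' Plain delimited text with columns `frequency_hz`, `ear`,
#' `threshold_db_hl`, `flag` (and optionally `subject`).
#'
#' @param x audiogram data.frame.
#' @param path file path.
#' @return `read_audiogram()` returns the audiogram data.frame.
#' @export
write_audiogram <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_audiogram
#' @export
read_audiogram <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frequency_hz", "ear", "threshold_db_hl")
  if (!all(need %in% names(out))) {
    stop("audiogram file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out
}
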