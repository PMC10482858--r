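#' Comparison frequencies
#'
#' The ten frequencies at which the staircase (M1) and GP (M2) audiograms
#' are compared and averaged into the pure-tone average (PTA).
#'
#' @return numeric vector of 10 frequencies, Hz.
#' @export
comparison_frequencies <- function() {
  c(250, 500, 750, 1000, 1500, 2000, 3000, 4000, 6000, 8000)
}

#' Resample a continuous threshold curve at standard frequencies
#'
#' Linear interpolation in log-frequency (octaves) of the GP threshold
#' curve at the requested frequencies. Frequencies outside the curve's
#' range are an error, never extrapolated.
#'
#' @param curve a `"threshold_curve"` (or data.frame with `frequency_hz`,
#'   `threshold_db_hl`).
#' @param freqs_hz frequencies at which to read the curve.
#' @return thresholds in dB HL at `freqs_hz`.
#' @export
resample_m2_at_standard <- function(curve, freqs_hz = comparison_frequencies()) {
  rng <- range(curve$frequency_hz)
  if (any(freqs_hz < rng[1] | freqs_hz > rng[2])) {
    stop(sprintf("requested frequency outside the curve range [%.5g, %.5g] Hz",
                 rng[1], rng[2]), call. = FALSE)
  }
  stats::approx(log2(curve$frequency_hz), curve$threshold_db_hl,
                xout = log2(freqs_hz), ties = "ordered")$y
}

#' Clip staircase thresholds to the in-situ floor
#'
#' Standard audiometry reaches below 10 dB HL but the in-situ method cannot,
#' so for comparison the staircase values are limited to the 10 dB HL floor:
#' elementwise `max(value, floor)`.
#'
#' @param values thresholds in dB HL.
#' @param floor_db the floor (default 10 dB HL).
#' @return clipped thresholds.
#' @export
clip_m1_floor <- function(values, floor_db = 10) {
  pmax(values, floor_db)
}

#' Build the method-difference table
#'
#' Aligns the staircase audiograms (M1) with the GP threshold curves (M2)
#' at the ten comparison frequencies: M1 is clipped to the 10 dB HL floor,
#' M2 is resampled from the continuous curve, and `diff = M2 - M1` is
#' formed per subject, ear and frequency, along with per-subject, per-ear
#' PTAs (unweighted means over exactly the ten frequencies).
#'
#' @param m1 data.frame with columns `subject`, `ear`, `frequency_hz`,
#'   `threshold_db_hl` (staircase audiograms; extra frequencies are
#'   ignored, the ten comparison frequencies must be present).
#' @param m2 either a data.frame in the same schema (already sampled), or a
#'   nested named list `m2[[subject]][[ear]]` of `"threshold_curve"`
#'   objects.
#' @param floor_db floor applied to M1, see [clip_m1_floor()].
#' @return object of class `"diff_table"`: list with `by_frequency` (long
#'   data.frame: `subject`, `ear`, `frequency_hz`, `m1_db`, `m2_db`,
#'   `diff_db`) and `pta` (`subject`, `ear`, `pta_m1`, `pta_m2`,
#'   `pta_diff`).
#' @export
build_diff_table <- function(m1, m2, floor_db = 10) {
  freqs <- comparison_frequencies()
  need <- c("subject", "ear", "frequency_hz", "threshold_db_hl")
  if (!all(need %in% names(m1))) {
    stop("`m1` must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  m1 <- m1[m1$frequency_hz %in% freqs, need]

  if (is.data.frame(m2)) {
    m2 <- m2[m2$frequency_hz %in% freqs, need]
  } else {
    rows <- list()
    for (subject in names(m2)) {
      for (ear in names(m2[[subject]])) {
        rows[[length(rows) + 1L]] <- data.frame(
          subject = subject, ear = ear, frequency_hz = freqs,
          threshold_db_hl = resample_m2_at_standard(m2[[subject]][[ear]], freqs),
          stringsAsFactors = FALSE
        )
      }
    }
    m2 <- do.call(rbind, rows)
  }

  key <- function(d) paste(d$subject, d$ear, d$frequency_hz, sep = "\r")
  m1 <- m1[order(m1$subject, m1$ear, m1$frequency_hz), ]
  m2 <- m2[order(m2$subject, m2$ear, m2$frequency_hz), ]
  missing_in_m2 <- setdiff(key(m1), key(m2))
  missing_in_m1 <- setdiff(key(m2), key(m1))
  if (length(missing_in_m2) || length(missing_in_m1)) {
    ids <- unique(c(
      vapply(strsplit(missing_in_m2, "\r"), `[`, "", 1L),
      vapply(strsplit(missing_in_m1, "\r"), `[`, "", 1L)
    ))
    stop("M1/M2 subject-ear-frequency sets do not match; unpaired subjects: ",
         paste(sort(ids), collapse = ", "), call. = FALSE)
  }

  by_freq <- data.frame(
    subject = m1$subject, ear = m1$ear, frequency_hz = m1$frequency_hz,
    m1_db = clip_m1_floor(m1$threshold_db_hl, floor_db),
    m2_db = m2$threshold_db_hl,
    stringsAsFactors = FALSE
  )
  by_freq$diff_db <- by_freq$m2_db - by_freq$m1_db

  agg <- function(col) {
    stats::aggregate(by_freq[[col]],
                     by = list(subject = by_freq$subject, ear = by_freq$ear),
                     FUN = mean)
  }
  counts <- stats::aggregate(by_freq$frequency_hz,
                             by = list(subject = by_freq$subject, ear = by_freq$ear),
                             FUN = length)
  if (any(counts$x != length(freqs))) {
    stop("each subject-ear must contribute exactly the ", length(freqs),
         " comparison frequencies", call. = FALSE)
  }
  pta <- agg("m1_db")
  names(pta)[3] <- "pta_m1"
  pta$pta_m2 <- agg("m2_db")$x
  pta$pta_diff <- pta$pta_m2 - pta$pta_m1
  structure(list(by_frequency = by_freq, pta = pta), class = "diff_table")
}

#' @export
print.diff_table <- function(x, ...) {
  cat(sprintf(
    "diff table: %d subject-ears x %d frequencies; mean PTA diff %.2f dB\n",
    nrow(x$pta), length(unique(x$by_frequency$frequency_hz)),
    mean(x$pta$pta_diff)
  ))
  invisible(x)
}

#' One-sample t test with Student confidence interval
#'
#' Standard two-sided one-sample t test against `null_mean`, reporting the
#' test statistic, degrees of freedom, p-value, the confidence interval at
#' the requested level, and the sample sd / standard error.
#'
#' @param values numeric sample (n >= 2).
#' @param null_mean hypothesized mean.
#' @param ci_level confidence level (e.g. 0.95 or 0.99).
#' @return list with `t_stat`, `df`, `p`, `ci_low`, `ci_high`, `mean`,
#'   `sd`, `serr`, `n`.
#' @export
one_sample_t <- function(values, null_mean = 0, ci_level = 0.95) {
  stopifnot(length(values) >= 2, ci_level > 0, ci_level < 1)
  s <- stats::sd(values)
  if (s == 0) {
    stop("degenerate sample: zero standard deviation", call. = FALSE)
  }
  tt <- stats::t.test(values, mu = null_mean, conf.level = ci_level)
  list(
    t_stat = unname(tt$statistic),
    df = unname(tt$parameter),
    p = tt$p.value,
    ci_low = tt$conf.int[1],
    ci_high = tt$conf.int[2],
    mean = mean(values),
    sd = s,
    serr = s / sqrt(length(values)),
    n = length(values)
  )
}

# Lilliefors KS statistic: empirical cdf vs the normal fitted by sample
# mean and sd
lilliefors_statistic <- function(values) {
  n <- length(values)
  z <- stats::pnorm(sort(values), mean(values), stats::sd(values))
  i <- seq_len(n)
  max(i / n - z, z - (i - 1) / n)
}

#' Monte Carlo critical value for the Lilliefors test
#'
#' The null distribution of the Lilliefors statistic depends only on the
#' sample size, so the critical value is computed by a seeded Monte Carlo
#' over standard-normal samples of the same n: reproducible bit-for-bit
#' given `rng_seed` and valid for any n (no published-table lookup).
#'
#' @param n sample size.
#' @param alpha significance level.
#' @param mc_reps Monte Carlo replicates.
#' @param rng_seed seed of the Monte Carlo.
#' @return critical value (upper `alpha` quantile of the null statistic).
#' @export
lilliefors_critical <- function(n, alpha = 0.05, mc_reps = 1e4, rng_seed = 1L) {
  stopifnot(n >= 4, alpha > 0, alpha < 1, mc_reps >= 100)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(rng_seed)
  x <- matrix(stats::rnorm(n * mc_reps), nrow = n)
  xs <- apply(x, 2L, sort)
  mu <- colMeans(xs)
  sdv <- sqrt((colSums(xs^2) - n * mu^2) / (n - 1))
  i <- seq_len(n)
  z <- stats::pnorm((xs - rep(mu, each = n)) / rep(sdv, each = n))
  d <- pmax(
    apply(i / n - z, 2L, max),
    apply(z - (i - 1) / n, 2L, max)
  )
  unname(stats::quantile(d, 1 - alpha))
}

#' Lilliefors normality test
#'
#' Kolmogorov-Smirnov-type test of composite normality (mean and variance
#' estimated from the sample), with the critical value obtained by seeded
#' Monte Carlo ([lilliefors_critical()]).
#'
#' @param values numeric sample (n >= 4).
#' @inheritParams lilliefors_critical
#' @return list with `reject` (logical), `statistic`, `critical_value`,
#'   `alpha`, `n`.
#' @export
lilliefors <- function(values, alpha = 0.05, mc_reps = 1e4, rng_seed = 1L) {
  if (length(values) < 4) stop("need at least 4 observations", call. = FALSE)
  stat <- lilliefors_statistic(values)
  crit <- lilliefors_critical(length(values), alpha, mc_reps, rng_seed)
  list(
    reject = stat > crit,
    statistic = stat,
    critical_value = crit,
    alpha = alpha,
    n = length(values)
  )
}

#' Dimension of the space spanned by group means (sequential MANOVA)
#'
#' One-way MANOVA dimensionality test: eigenvalues of `W^{-1} B` (within-
#' and between-group SSCP matrices) feed a sequence of Wilks' lambda
#' statistics with Bartlett's chi-square approximation; the estimated
#' dimension `d` is the smallest dimension whose test is non-significant at
#' `alpha`. `d = 0` means the group means are indistinguishable; `d = 1`
#' that they differ along a line.
#'
#' @param groups list of numeric matrices (rows = observations, columns =
#'   the common set of variables), one per group.
#' @param alpha significance level of each sequential test.
#' @return list with `d`, `p_values` (tests of dimension 0, 1, ...),
#'   `eigenvalues`, `statistics` (Bartlett chi-squares), `df`.
#' @export
manova_dimension <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2)
  groups <- lapply(groups, as.matrix)
  p <- ncol(groups[[1]])
  if (!all(vapply(groups, ncol, 0L) == p)) {
    stop("all groups must have the same number of variables", call. = FALSE)
  }
  g <- length(groups)
  ns <- vapply(groups, nrow, 0L)
  n <- sum(ns)
  if (n <= p + g) {
    stop("not enough observations for ", p, " variables and ", g, " groups",
         call. = FALSE)
  }
  means <- lapply(groups, colMeans)
  grand <- Reduce(`+`, mapply(function(m, k) m * k, means, ns,
                              SIMPLIFY = FALSE)) / n
  W <- Reduce(`+`, lapply(groups, function(x) {
    c <- sweep(x, 2L, colMeans(x))
    crossprod(c)
  }))
  B <- Reduce(`+`, mapply(function(m, k) k * tcrossprod(m - grand),
                          means, ns, SIMPLIFY = FALSE))
  R <- tryCatch(chol(W), error = function(e) {
    stop("within-group covariance is singular (deficient variables or too few rows)",
         call. = FALSE)
  })
  Ri <- backsolve(R, diag(p))
  lambda <- sort(pmax(eigen(t(Ri) %*% B %*% Ri, symmetric = TRUE)$values, 0),
                 decreasing = TRUE)
  s <- min(p, g - 1)
  lambda <- lambda[seq_len(s)]

  stats_ <- p_values <- dfs <- numeric(s)
  for (d in 0:(s - 1)) {
    wilks <- prod(1 / (1 + lambda[(d + 1):s]))
    chi2 <- -(n - 1 - (p + g) / 2) * log(wilks)
    df <- (p - d) * (g - 1 - d)
    stats_[d + 1] <- chi2
    dfs[d + 1] <- df
    p_values[d + 1] <- stats::pchisq(chi2, df, lower.tail = FALSE)
  }
  d_hat <- if (any(p_values > alpha)) which(p_values > alpha)[1] - 1L else s
  list(d = d_hat, p_values = p_values, eigenvalues = lambda,
       statistics = stats_, df = dfs)
}

#' Probability that a future difference falls within a band
#'
#' Credible-interval analysis of method differences under a normal model
#' with the Jeffreys (uninformative) prior: the posterior predictive for a
#' future difference is Student-t with `n - 1` degrees of freedom, located
#' at the sample mean with scale `sd * sqrt(1 + 1/n)`. Returns the
#' posterior predictive probability that a future difference lies within
#' `half_width` of the sample mean.
#'
#' @param diffs observed differences (n >= 3).
#' @param half_width_db half-width of the interval around the mean
#'   (default 10 dB).
#' @return probability in `[0, 1]` (1 when the sample has zero spread).
#' @export
credible_interval_prob <- function(diffs, half_width_db = 10) {
  stopifnot(length(diffs) >= 3, half_width_db > 0)
  s <- stats::sd(diffs)
  if (s == 0) return(1)
  n <- length(diffs)
  scale <- s * sqrt(1 + 1 / n)
  2 * stats::pt(half_width_db / scale, df = n - 1) - 1
}

#' The per-subject PTA table of the clinical comparison
#'
#' Loads the embedded 35-subject fixture of per-ear pure-tone averages for
#' the staircase method (`hl_left`, `hl_right`), the GP method (`gp_left`,
#' `gp_right`) and their differences (GP minus staircase), in dB HL, and
#' validates its integrity (35 records; printed differences consistent with
#' the printed PTAs to within rounding).
#'
#' @return data.frame of class `"table2_fixture"` with 35 rows.
#' @export
table2_fixture <- function() {
  path <- system.file("extdata", "table2_pta.csv", package = "audiogp",
                      mustWork = TRUE)
  x <- utils::read.csv(path)
  stopifnot(nrow(x) == 35L)
  slack_l <- max(abs((x$gp_left - x$hl_left) - x$diff_left))
  slack_r <- max(abs((x$gp_right - x$hl_right) - x$diff_right))
  if (max(slack_l, slack_r) > 0.15) {
    stop("fixture integrity check failed: differences inconsistent with PTAs",
         call. = FALSE)
  }
  structure(x, class = c("table2_fixture", "data.frame"))
}

#' Summary rows of the PTA comparison table
#'
#' Recomputes, for every column of the fixture, the count, mean, standard
#' deviation, standard error and the normal-critical-value confidence
#' interval `mean -/+ tc * serr` (tc = 1.96 for 95%).
#'
#' @param fixture the [table2_fixture()] (or any data.frame of numeric
#'   columns).
#' @param tc critical value multiplying the standard error.
#' @return data.frame with one row per column: `column`, `count`, `mean`,
#'   `sd`, `serr`, `ci_low`, `ci_high`.
#' @export
table2_summary <- function(fixture = table2_fixture(), tc = 1.96) {
  cols <- setdiff(names(fixture), "dataset")
  out <- lapply(cols, function(cn) {
    v <- fixture[[cn]]
    m <- mean(v)
    s <- stats::sd(v)
    se <- s / sqrt(length(v))
    data.frame(
      column = cn, count = length(v), mean = m, sd = s, serr = se,
      ci_low = m - tc * se, ci_high = m + tc * se,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
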