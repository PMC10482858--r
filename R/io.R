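#' Serialize a session to JSON
#'
#' Writes the session record as plain JSON: the configuration block, the
#' per-ear ordered trial arrays (frequency, level, response) and the per-ear
#' threshold curves. Numbers are written at full precision, so reading the
#' file back and refitting reproduces the curves exactly.
#'
#' @param result a list with `state` and `curves`, as returned by
#'   [run_session()] (a bare `"session_state"` is also accepted).
#' @param path output file.
#' @param subject optional subject identifier stored in the record.
#' @return `path`, invisibly.
#' @export
write_session <- function(result, path, subject = NULL) {
  if (inherits(result, "session_state")) {
    result <- list(state = result, curves = NULL)
  }
  state <- result$state
  cfg <- state$config
  record <- list(
    subject = subject,
    config = list(
      freq_range_hz = cfg$freq_range_hz,
      level_range_db = cfg$level_range_db,
      grid_freq_step_oct = cfg$grid_freq_step_oct,
      grid_level_step_db = cfg$grid_level_step_db,
      seed_tones = cfg$seed_tones,
      budget_per_ear = cfg$budget_per_ear,
      early_stop_tol = cfg$early_stop_tol,
      acquisition = cfg$acquisition,
      random_seed = cfg$random_seed,
      kernel = unclass(cfg$kernel),
      mean = unclass(cfg$mean),
      link = unclass(cfg$link),
      level_scale = cfg$level_scale
    ),
    trials = lapply(state$trials, function(tr) {
      tr[, c("frequency_hz", "level_db_hl", "response")]
    }),
    curves = lapply(result$curves, as.data.frame)
  )
  jsonlite::write_json(record, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' Read a session record back
#'
#' @param path a session JSON written by [write_session()].
#' @return list with `subject`, `config` (a [session_config()]), `trials`
#'   (per-ear data.frames) and `curves` (as stored; possibly `NULL`).
#' @export
read_session <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfgj <- rec$config
  config <- session_config(
    freq_range_hz = cfgj$freq_range_hz,
    level_range_db = cfgj$level_range_db,
    grid_freq_step_oct = cfgj$grid_freq_step_oct,
    grid_level_step_db = cfgj$grid_level_step_db,
    seed_tones = as.data.frame(cfgj$seed_tones),
    budget_per_ear = cfgj$budget_per_ear,
    early_stop_tol = cfgj$early_stop_tol,
    acquisition = cfgj$acquisition,
    random_seed = cfgj$random_seed,
    kernel = do.call(kernel_params, cfgj$kernel),
    mean = do.call(mean_params, cfgj$mean),
    link = do.call(link_params, cfgj$link),
    level_scale = cfgj$level_scale
  )
  trials <- lapply(rec$trials, function(tr) {
    tr <- as.data.frame(tr)
    if (!nrow(tr)) return(empty_trials())
    tr$response <- as.integer(tr$response)
    tr
  })
  list(subject = rec$subject, config = config, trials = trials,
       curves = rec$curves)
}

#' Refit a recorded session
#'
#' Replays the per-ear trial lists of a stored session through
#' [laplace_fit()] and re-extracts the threshold curves; because the fit is
#' deterministic, the curves equal the ones extracted live.
#'
#' @param path a session JSON file.
#' @return list with `subject`, `config`, `state` and `curves`.
#' @export
replay_session <- function(path) {
  rec <- read_session(path)
  state <- new_session(rec$config)
  curves <- list()
  for (ear in names(rec$trials)) {
    tr <- rec$trials[[ear]]
    if (!nrow(tr)) next
    tr$ear <- ear
    state$trials[[ear]] <- tr
    state$posterior[[ear]] <- laplace_fit(
      tr, kernel = rec$config$kernel, mean = rec$config$mean,
      link = rec$config$link, level_scale = rec$config$level_scale
    )
    curves[[ear]] <- extract_threshold(state$posterior[[ear]], rec$config)
  }
  list(subject = rec$subject, config = rec$config, state = state,
       curves = curves)
}

write_manifest <- function(out_dir, command, config, seeds, files) {
  manifest <- list(
    command = command,
    package = "audiogp",
    version = as.character(utils::packageVersion("audiogp")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seeds = seeds,
    config = config,
    files = data.frame(
      path = basename(files),
      md5 = unname(tools::md5sum(files)),
      stringsAsFactors = FALSE
    )
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Simulate paired staircase and GP sessions
#'
#' For each seed, builds the phenotype listener, runs one active GP session
#' (M2) and one standard staircase audiogram (M1), and writes a session
#' JSON plus an audiogram CSV; a manifest with content hashes of every
#' output closes the run. Both methods test the same simulated listener, so
#' the output pair is the synthetic analogue of one study subject.
#'
#' @param phenotype phenotype name, see [make_phenotype()].
#' @param seeds integer vector; one subject is simulated per seed.
#' @param out_dir output directory (created if missing).
#' @param config a [session_config()]; its `random_seed` is replaced by
#'   each subject's seed.
#' @param ears ears to test.
#' @return data.frame listing the written files (invisibly).
#' @export
cli_simulate <- function(phenotype, seeds, out_dir,
                         config = session_config(),
                         ears = c("left", "right")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (seed in seeds) {
    subject <- sprintf("%s_%03d", phenotype, seed)
    message(sprintf("simulating subject %s (seed %d)", subject, seed))
    profile <- make_phenotype(phenotype, rng_seed = seed)
    cfg <- config
    cfg$random_seed <- as.integer(seed)
    res <- run_session(make_responder(profile), cfg, ears = ears)
    spath <- file.path(out_dir, paste0("session_", subject, ".json"))
    write_session(res, spath, subject = subject)

    m1 <- standard_audiogram(profile, ears = ears)
    m1$subject <- subject
    apath <- file.path(out_dir, paste0("audiogram_", subject, ".csv"))
    write_audiogram(m1, apath)
    files <- c(files, spath, apath)
  }
  write_manifest(out_dir, "simulate",
                 list(phenotype = phenotype, ears = ears,
                      budget_per_ear = config$budget_per_ear,
                      acquisition = config$acquisition),
                 seeds, files)
  invisible(data.frame(path = files, stringsAsFactors = FALSE))
}

safe_stat <- function(expr) {
  tryCatch(expr, error = function(e) list(error = conditionMessage(e)))
}

#' Compare staircase and GP results across subjects
#'
#' Builds the M2-minus-M1 difference table from staircase audiogram CSVs
#' and recorded GP sessions, then runs the full comparison pipeline per
#' ear: one-sample t tests (95% and 99% CI) on the PTA differences, the
#' Lilliefors normality test, the MANOVA dimension test between the M1 and
#' M2 per-frequency threshold matrices, and credible-interval probabilities
#' (within 10 dB) per frequency and for the PTA. The report is written as
#' JSON keyed by test name.
#'
#' @param m1_csv path(s) to audiogram CSVs with a `subject` column.
#' @param m2_sessions paths to session JSON files (subject ids stored
#'   inside), or a directory containing them.
#' @param out_report path of the JSON report to write.
#' @param rng_seed seed for the Lilliefors Monte Carlo.
#' @return the report list, invisibly.
#' @export
cli_analyze <- function(m1_csv, m2_sessions, out_report, rng_seed = 1L) {
  m1 <- do.call(rbind, lapply(m1_csv, read_audiogram))
  if (is.null(m1$subject)) {
    stop("audiogram CSV must carry a `subject` column", call. = FALSE)
  }
  if (length(m2_sessions) == 1L && dir.exists(m2_sessions)) {
    m2_sessions <- list.files(m2_sessions, pattern = "^session_.*\\.json$",
                              full.names = TRUE)
  }
  m2 <- list()
  for (path in m2_sessions) {
    rep_ <- replay_session(path)
    if (is.null(rep_$subject)) {
      stop("session file ", path, " carries no subject id", call. = FALSE)
    }
    m2[[rep_$subject]] <- rep_$curves
  }
  m1_subjects <- sort(unique(m1$subject))
  m2_subjects <- sort(names(m2))
  unpaired <- c(setdiff(m1_subjects, m2_subjects),
                setdiff(m2_subjects, m1_subjects))
  if (length(unpaired)) {
    stop("subjects present in only one input: ",
         paste(unpaired, collapse = ", "), call. = FALSE)
  }

  dt <- build_diff_table(m1, m2)
  report <- list(n_subjects = length(m1_subjects))
  for (ear in intersect(c("left", "right"), unique(dt$pta$ear))) {
    pta <- dt$pta[dt$pta$ear == ear, ]
    bf <- dt$by_frequency[dt$by_frequency$ear == ear, ]
    freqs <- sort(unique(bf$frequency_hz))
    ci_by_freq <- vapply(freqs, function(f) {
      safe_num(credible_interval_prob(bf$diff_db[bf$frequency_hz == f]))
    }, numeric(1))
    report[[ear]] <- list(
      mean_pta_diff = mean(pta$pta_diff),
      sd_pta_diff = stats::sd(pta$pta_diff),
      t_test = list(
        ci95 = safe_stat(one_sample_t(pta$pta_diff, ci_level = 0.95)),
        ci99 = safe_stat(one_sample_t(pta$pta_diff, ci_level = 0.99))
      ),
      lilliefors = safe_stat(lilliefors(pta$pta_diff, rng_seed = rng_seed)),
      manova = safe_stat(manova_dimension(list(
        m1_matrix(bf, "m1_db"), m1_matrix(bf, "m2_db")
      ))),
      credible_intervals = c(
        stats::setNames(as.list(ci_by_freq), paste0("f", freqs)),
        list(pta = safe_num(credible_interval_prob(pta$pta_diff)))
      )
    )
  }
  jsonlite::write_json(report, out_report, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  message("report written to ", out_report)
  invisible(report)
}

safe_num <- function(expr) {
  tryCatch(expr, error = function(e) NA_real_)
}

# wide subject x frequency matrix of one value column
m1_matrix <- function(bf, col) {
  w <- stats::reshape(
    bf[, c("subject", "frequency_hz", col)],
    idvar = "subject", timevar = "frequency_hz", direction = "wide"
  )
  as.matrix(w[, -1, drop = FALSE])
}

# the printed summary rows of the clinical PTA comparison table, used as the
# comparison baseline by cli_reproduce_table2()
printed_table2_summary <- function() {
  data.frame(
    column = c("hl_left", "hl_right", "gp_left", "gp_right",
               "diff_left", "diff_right"),
    mean = c(17.2, 17.9, 20.9, 20.7, 3.8, 2.8),
    sd = c(9.17, 9.96, 10.31, 10.68, 7.16, 7.92),
    serr = c(1.55, 1.68, 1.74, 1.81, 1.21, 1.34),
    ci_high = c(20.2, 21.2, 24.4, 24.2, 6.2, 5.5),
    ci_low = c(14.1, 14.6, 17.5, 17.2, 1.4, 0.2),
    stringsAsFactors = FALSE
  )
}

#' Recompute the clinical PTA summary table
#'
#' Recomputes every summary row (count, mean, sd, serr, 95% CI at
#' tc = 1.96) of the embedded 35-subject PTA comparison fixture, plus the
#' one-sample t tests and Lilliefors tests on the two difference columns,
#' and writes them side by side with the printed values and their absolute
#' deviations. The command is fully deterministic, so repeated runs produce
#' byte-identical reports.
#'
#' @param out_report path of the JSON report to write.
#' @return the report list, invisibly.
#' @export
cli_reproduce_table2 <- function(out_report) {
  fx <- table2_fixture()
  recomputed <- table2_summary(fx)
  printed <- printed_table2_summary()
  stopifnot(identical(recomputed$column, printed$column))
  comparison <- lapply(seq_len(nrow(printed)), function(i) {
    list(
      column = printed$column[i],
      recomputed = as.list(recomputed[i, c("mean", "sd", "serr",
                                           "ci_low", "ci_high")]),
      printed = as.list(printed[i, c("mean", "sd", "serr",
                                     "ci_low", "ci_high")]),
      abs_deviation = as.list(abs(
        unlist(recomputed[i, c("mean", "sd", "serr", "ci_low", "ci_high")]) -
          unlist(printed[i, c("mean", "sd", "serr", "ci_low", "ci_high")])
      ))
    )
  })
  tests <- lapply(list(diff_left = fx$diff_left, diff_right = fx$diff_right),
                  function(v) {
    list(
      t_test_95 = one_sample_t(v, ci_level = 0.95),
      t_test_99 = one_sample_t(v, ci_level = 0.99),
      lilliefors = lilliefors(v, rng_seed = 1L)
    )
  })
  report <- list(count = nrow(fx), summary = comparison, tests = tests)
  jsonlite::write_json(report, out_report, auto_unbox = TRUE, digits = NA)
  message("report written to ", out_report)
  invisible(report)
}
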