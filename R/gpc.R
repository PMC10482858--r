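#' Trial records
#'
#' A trial is the 3-tuple (frequency, level in dB HL, response label), with
#' the ear it was delivered to. Labels are exactly `1` = heard, `0` = not
#' heard. Collections of trials are plain data frames with columns
#' `frequency_hz`, `level_db_hl`, `response`, `ear`, so they read and write
#' naturally as delimited text.
#'
#' @param frequency_hz tone frequency in Hz.
#' @param level_db_hl tone level in dB HL.
#' @param response 1 (heard) or 0 (not heard).
#' @param ear `"left"` or `"right"`.
#' @return a one-row data.frame of class `c("trial_record", "data.frame")`.
#' @export
trial_record <- function(frequency_hz, level_db_hl, response, ear = "left") {
  check_labels(response)
  ear <- match.arg(ear, c("left", "right"))
  structure(
    data.frame(
      frequency_hz = frequency_hz, level_db_hl = level_db_hl,
      response = as.integer(response), ear = ear,
      stringsAsFactors = FALSE
    ),
    class = c("trial_record", "data.frame")
  )
}

check_labels <- function(response) {
  if (length(response) && !all(response %in% c(0L, 1L))) {
    stop("response labels must be 0 (not heard) or 1 (heard)", call. = FALSE)
  }
  invisible(response)
}

empty_trials <- function() {
  data.frame(
    frequency_hz = numeric(0), level_db_hl = numeric(0),
    response = integer(0), ear = character(0), stringsAsFactors = FALSE
  )
}

# log-likelihood, its first and (negated) second derivative wrt the latent,
# for Bernoulli responses through the generalized logistic link.
bernoulli_link_terms <- function(f, y, link) {
  k <- link$steepness
  s <- stats::plogis(k * (f - link$midpoint))
  L <- link$max_value
  u <- s * (1 - s)
  ll <- ifelse(y == 1, log(L) + stats::plogis(k * (f - link$midpoint), log.p = TRUE),
               log1p(-L * s))
  dll <- ifelse(y == 1, k * (1 - s), -k * L * u / (1 - L * s))
  w <- ifelse(y == 1, k^2 * u,
              k^2 * L * (u * (1 - 2 * s) * (1 - L * s) + L * u^2) / (1 - L * s)^2)
  list(ll = ll, dll = dll, w = pmax(w, 0))
}

#' Fit the tone-space classifier by Laplace approximation
#'
#' Places a GP prior (squared-exponential kernel on the scaled tone
#' coordinates, affine-in-level mean) on a latent audibility function and
#' fits the Bernoulli-logistic likelihood of the observed heard/not-heard
#' labels by a Laplace approximation: Newton iterations locate the posterior
#' mode and the local curvature supplies the Gaussian approximation.
#' Deterministic for fixed inputs.
#'
#' @param trials data.frame of trials (one ear) with columns `frequency_hz`,
#'   `level_db_hl`, `response`; may be empty, in which case the posterior is
#'   the prior.
#' @param kernel,mean,link parameter bundles, see [kernel_params()].
#' @param level_scale dB per scaled level unit.
#' @param tol convergence tolerance on the max-norm of the Laplace-objective
#'   gradient.
#' @param max_iter maximum Newton iterations.
#' @param jitter diagonal jitter added to the kernel matrix (permits
#'   duplicate stimuli).
#' @return an object of class `"gp_posterior"`.
#' @examples
#' tr <- rbind(
#'   trial_record(1000, 60, 1),
#'   trial_record(1000, 20, 0)
#' )
#' fit <- laplace_fit(tr)
#' predict(fit, data.frame(frequency_hz = 1000, level_db_hl = 40))
#' @export
laplace_fit <- function(trials,
                        kernel = kernel_params(),
                        mean = mean_params(),
                        link = link_params(),
                        level_scale = 20,
                        tol = 1e-6,
                        max_iter = 100,
                        jitter = 1e-8) {
  if (is.null(trials)) trials <- empty_trials()
  stopifnot(tol > 0, max_iter >= 1)
  check_labels(trials$response)
  n <- nrow(trials)
  post <- structure(
    list(
      trials = trials, kernel = kernel, mean = mean, link = link,
      level_scale = level_scale, jitter = jitter,
      converged = TRUE, residual = 0, iterations = 0L
    ),
    class = "gp_posterior"
  )
  if (n == 0L) {
    post$coords <- tone_coords(numeric(0), numeric(0), level_scale)
    post$f_hat <- numeric(0)
    post$alpha <- numeric(0)
    post$sqrt_w <- numeric(0)
    post$chol_b <- matrix(numeric(0), 0, 0)
    post$prior_mean <- numeric(0)
    return(post)
  }

  X <- tone_coords(trials$frequency_hz, trials$level_db_hl, level_scale)
  y <- as.integer(trials$response)
  K <- se_kernel_matrix(X, X, kernel) + diag(jitter, n)
  m <- prior_mean_at(X, mean, level_scale)

  f <- m
  a <- numeric(n)
  residual <- Inf
  iter <- 0L
  repeat {
    terms <- bernoulli_link_terms(f, y, link)
    residual <- max(abs(terms$dll - a))
    if (residual < tol || iter >= max_iter) break
    iter <- iter + 1L
    w <- terms$w
    sw <- sqrt(w)
    B <- diag(n) + (sw %o% sw) * K
    R <- chol(B)
    b <- w * (f - m) + terms$dll
    a <- b - sw * backsolve(R, forwardsolve(t(R), sw * (K %*% b)))
    a <- as.numeric(a)
    f <- m + as.numeric(K %*% a)
  }
  if (residual >= tol) {
    stop(sprintf(
      "Laplace fit did not converge in %d iterations (residual %.3g)",
      max_iter, residual
    ), call. = FALSE)
  }

  terms <- bernoulli_link_terms(f, y, link)
  sw <- sqrt(terms$w)
  R <- chol(diag(n) + (sw %o% sw) * K)

  post$coords <- X
  post$f_hat <- f
  post$alpha <- terms$dll    # equals K^{-1} (f_hat - m) at the mode
  post$sqrt_w <- sw
  post$chol_b <- R
  post$prior_mean <- m
  post$log_lik_at_mode <- sum(terms$ll)
  post$residual <- residual
  post$iterations <- iter
  post
}

#' @export
print.gp_posterior <- function(x, ...) {
  cat(sprintf(
    "Laplace GP audiogram posterior: %d trials (%d heard), %d Newton iterations\n",
    nrow(x$trials), sum(x$trials$response), x$iterations
  ))
  invisible(x)
}

# cached Gauss-Hermite rule (nodes for integral against exp(-x^2))
gauss_hermite_rule <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (is.null(cache[[key]])) cache[[key]] <<- pracma::gaussHermite(n)
    cache[[key]]
  }
})

# E[link(N(mu, sd^2))] by fixed-order Gauss-Hermite quadrature; vectorized
# over mu, sd.
link_expectation <- function(mu, sd, link, nodes = 32) {
  gh <- gauss_hermite_rule(nodes)
  z <- outer(sd * sqrt(2), gh$x) + mu     # n x nodes
  p <- logistic_link(z, link)
  as.numeric(p %*% gh$w) / sqrt(pi)
}

#' Predict audibility over the tone space
#'
#' Latent predictive mean and standard deviation from the Laplace posterior,
#' and the audibility probability as the expectation of the logistic link
#' over the latent predictive Gaussian, computed by fixed-order
#' Gauss-Hermite quadrature (32 nodes by default: deterministic, no
#' sampling).
#'
#' @param object a `"gp_posterior"` from [laplace_fit()].
#' @param newdata data.frame with columns `frequency_hz` and `level_db_hl`
#'   (or a single `tone_stimulus`).
#' @param gh_nodes Gauss-Hermite order for the predictive integral.
#' @param ... unused.
#' @return data.frame with one row per query: `frequency_hz`, `level_db_hl`,
#'   `probability`, `latent_mean`, `latent_sd`, and `extrapolated` (TRUE for
#'   queries outside the 125-8000 Hz x 10-80 dB HL tone space).
#' @export
predict.gp_posterior <- function(object, newdata, gh_nodes = 32, ...) {
  if (inherits(newdata, "tone_stimulus")) {
    newdata <- data.frame(
      frequency_hz = newdata$frequency_hz,
      level_db_hl = newdata$level_db_hl
    )
  }
  Xs <- tone_coords(newdata$frequency_hz, newdata$level_db_hl, object$level_scale)
  ms <- prior_mean_at(Xs, object$mean, object$level_scale)
  kss <- object$kernel$signal_variance
  n <- nrow(object$coords)
  if (n == 0L) {
    mu <- ms
    var <- rep(kss, nrow(Xs))
  } else {
    Ks <- se_kernel_matrix(object$coords, Xs, object$kernel)   # n x m
    mu <- ms + as.numeric(crossprod(Ks, object$alpha))
    v <- forwardsolve(t(object$chol_b), object$sqrt_w * Ks)
    var <- pmax(kss - colSums(v^2), 0)
  }
  sd <- sqrt(var)
  data.frame(
    frequency_hz = newdata$frequency_hz,
    level_db_hl = newdata$level_db_hl,
    probability = pmin(pmax(link_expectation(mu, sd, object$link, gh_nodes), 0), 1),
    latent_mean = mu,
    latent_sd = sd,
    extrapolated = newdata$frequency_hz < 125 | newdata$frequency_hz > 8000 |
      newdata$level_db_hl < 10 | newdata$level_db_hl > 80
  )
}

#' Laplace-approximate log marginal likelihood
#'
#' The Laplace evidence of the fitted classifier:
#' `log p(y | f_hat) - 1/2 (f_hat - m)' K^{-1} (f_hat - m) - 1/2 log|B|`.
#' Useful for comparing fixed hyperparameter candidates on the same trials.
#'
#' @param posterior a converged `"gp_posterior"`.
#' @return scalar log evidence (0 for an empty trial set).
#' @export
log_marginal_likelihood <- function(posterior) {
  stopifnot(inherits(posterior, "gp_posterior"))
  if (!isTRUE(posterior$converged) || posterior$residual >= 1e-3) {
    stop("posterior is not converged", call. = FALSE)
  }
  if (nrow(posterior$trials) == 0L) return(0)
  posterior$log_lik_at_mode -
    0.5 * sum(posterior$alpha * (posterior$f_hat - posterior$prior_mean)) -
    sum(log(diag(posterior$chol_b)))
}

#' Pick kernel hyperparameters by Laplace evidence on a grid
#'
#' Deterministic alternative to gradient-based hyperparameter optimization:
#' each candidate [kernel_params()] bundle is fitted to the same trials and
#' the one with the highest Laplace evidence wins. Ties go to the earliest
#' candidate.
#'
#' @param trials trial data.frame (one ear).
#' @param candidates list of [kernel_params()] bundles; the default is a
#'   small log-spaced grid around the package defaults.
#' @inheritParams laplace_fit
#' @return the winning `"kernel_params"` bundle, with the per-candidate
#'   evidences attached as attribute `"evidence"`.
#' @export
select_kernel_by_evidence <- function(trials, candidates = NULL,
                                      mean = mean_params(), link = link_params(),
                                      level_scale = 20) {
  if (is.null(candidates)) {
    grid <- expand.grid(sv = c(1, 4, 16), lf = c(0.5, 1, 2), ll = c(0.5, 1, 2))
    candidates <- lapply(seq_len(nrow(grid)), function(i) {
      kernel_params(grid$sv[i], grid$lf[i], grid$ll[i])
    })
  }
  ev <- vapply(candidates, function(k) {
    log_marginal_likelihood(
      laplace_fit(trials, kernel = k, mean = mean, link = link,
                  level_scale = level_scale)
    )
  }, numeric(1))
  best <- candidates[[which.max(ev)]]
  attr(best, "evidence") <- ev
  best
}
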