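# Independent oracles for the GP classifier, deliberately avoiding the
# package's Laplace/Newton and vectorized-kernel code paths: covariances are
# assembled pairwise from the scalar kernel, the prior mean is written out
# from its definition, and the exact (non-Gaussian) posterior is integrated
# by brute force on a dense grid. A fixed-point iteration provides the
# single-observation posterior mode.

oracle_kernel_matrix <- function(ca, cb, kernel) {
  outer(seq_len(nrow(ca)), seq_len(nrow(cb)),
        Vectorize(function(i, j) se_kernel(ca[i, ], cb[j, ], kernel)))
}

oracle_prior_mean <- function(coords, mean, level_scale) {
  mean$offset + mean$level_slope *
    (coords[, 2] - mean$ref_level_db / level_scale)
}

# exact predictive P(heard) at `query` given `trials`, by tensor-grid
# quadrature over the latent values at the training points
oracle_predictive <- function(trials, query,
                              kernel = kernel_params(),
                              mean = mean_params(),
                              link = link_params(),
                              level_scale = 20,
                              grid_pts = 61, span = 6, gh_nodes = 40) {
  X <- tone_coords(trials$frequency_hz, trials$level_db_hl, level_scale)
  y <- trials$response
  n <- nrow(X)
  K <- oracle_kernel_matrix(X, X, kernel) + diag(1e-8, n)
  m <- oracle_prior_mean(X, mean, level_scale)
  Xs <- tone_coords(query$frequency_hz, query$level_db_hl, level_scale)
  ms <- oracle_prior_mean(Xs, mean, level_scale)
  Ks <- oracle_kernel_matrix(X, Xs, kernel)
  Kinv <- solve(K)

  sds <- sqrt(diag(K))
  axes <- lapply(seq_len(n), function(i) {
    seq(m[i] - span * sds[i], m[i] + span * sds[i], length.out = grid_pts)
  })
  grid <- as.matrix(expand.grid(axes))
  D <- sweep(grid, 2L, m)
  logw <- -0.5 * rowSums((D %*% Kinv) * D)
  for (i in seq_len(n)) {
    p <- logistic_link(grid[, i], link)
    logw <- logw + if (y[i] == 1) log(p) else log1p(-p)
  }
  w <- exp(logw - max(logw))

  A <- Kinv %*% Ks                                   # n x m
  cond_mu <- sweep(D %*% A, 2L, ms, "+")             # grid x m
  cond_sd <- sqrt(pmax(kernel$signal_variance - colSums(Ks * (Kinv %*% Ks)), 0))
  gh <- pracma::gaussHermite(gh_nodes)
  vapply(seq_len(nrow(Xs)), function(j) {
    z <- outer(cond_mu[, j], sqrt(2) * cond_sd[j] * gh$x, "+")
    ep <- as.numeric(logistic_link(z, link) %*% gh$w) / sqrt(pi)
    sum(w * ep) / sum(w)
  }, numeric(1))
}

# exact evidence p(y) for a small trial set, same tensor-grid quadrature
oracle_evidence <- function(trials,
                            kernel = kernel_params(),
                            mean = mean_params(),
                            link = link_params(),
                            level_scale = 20,
                            grid_pts = 201, span = 7) {
  X <- tone_coords(trials$frequency_hz, trials$level_db_hl, level_scale)
  y <- trials$response
  n <- nrow(X)
  K <- oracle_kernel_matrix(X, X, kernel) + diag(1e-8, n)
  m <- oracle_prior_mean(X, mean, level_scale)
  Kinv <- solve(K)
  sds <- sqrt(diag(K))
  axes <- lapply(seq_len(n), function(i) {
    seq(m[i] - span * sds[i], m[i] + span * sds[i], length.out = grid_pts)
  })
  steps <- vapply(axes, function(a) a[2] - a[1], numeric(1))
  grid <- as.matrix(expand.grid(axes))
  D <- sweep(grid, 2L, m)
  dens <- exp(-0.5 * rowSums((D %*% Kinv) * D)) /
    sqrt((2 * pi)^n * det(K))
  lik <- rep(1, nrow(grid))
  for (i in seq_len(n)) {
    p <- logistic_link(grid[, i], link)
    lik <- lik * (if (y[i] == 1) p else 1 - p)
  }
  log(sum(dens * lik) * prod(steps))
}

# posterior mode of the single-observation problem by damped fixed-point
# iteration on f = m + k * (y - sigma(f))
oracle_mode_1pt <- function(y, m = 0, k = 1, iters = 400) {
  f <- m
  for (i in seq_len(iters)) f <- 0.5 * f + 0.5 * (m + k * (y - stats::plogis(f)))
  f
}

# deterministic step-observer listener, flat threshold
noiseless_listener <- function(threshold_db, rng_seed = 1L) {
  listener_profile(
    data.frame(frequency_hz = c(125, 8000), threshold_db_hl = threshold_db),
    psychometric_slope = Inf, guess_rate = 0, lapse_rate = 0,
    rng_seed = rng_seed
  )
}
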