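#' Tone stimuli and the scaled tone space
#'
#' Audiometric similarity is octave-based, so the GP works in scaled internal
#' coordinates: frequency is mapped to octaves above 125 Hz (`log2(f / 125)`)
#' and level (dB HL) is divided by a level scale (default 20 dB). With this
#' scaling, a unit kernel lengthscale in either dimension is meaningful: one
#' octave in frequency, 20 dB in level.
#'
#' @param frequency_hz tone frequency in Hz (strictly positive).
#' @param level_db_hl tone level in dB HL.
#' @param level_scale dB per scaled level unit (default 20).
#' @return `tone_stimulus()` returns an object of class `"tone_stimulus"`:
#'   a list with `frequency_hz`, `level_db_hl` and `coords`, the 2-vector of
#'   scaled coordinates `(octaves re 125 Hz, level / level_scale)`.
#' @examples
#' tone_stimulus(1000, 40)
#' @export
tone_stimulus <- function(frequency_hz, level_db_hl, level_scale = 20) {
  stopifnot(length(frequency_hz) == 1L, length(level_db_hl) == 1L)
  if (!is.finite(frequency_hz) || frequency_hz <= 0) {
    stop("`frequency_hz` must be strictly positive", call. = FALSE)
  }
  if (!is.finite(level_db_hl)) {
    stop("`level_db_hl` must be finite", call. = FALSE)
  }
  structure(
    list(
      frequency_hz = as.numeric(frequency_hz),
      level_db_hl = as.numeric(level_db_hl),
      coords = tone_coords(frequency_hz, level_db_hl, level_scale)
    ),
    class = "tone_stimulus"
  )
}

#' @rdname tone_stimulus
#' @return `tone_coords()` returns an n x 2 matrix of scaled coordinates;
#'   `tone_from_coords()` inverts it.
#' @export
tone_coords <- function(frequency_hz, level_db_hl, level_scale = 20) {
  stopifnot(level_scale > 0, all(frequency_hz > 0))
  cbind(octaves = log2(frequency_hz / 125), level = level_db_hl / level_scale)
}

#' @rdname tone_stimulus
#' @param coords matrix of scaled coordinates as produced by [tone_coords()].
#' @export
tone_from_coords <- function(coords, level_scale = 20) {
  coords <- rbind(coords)
  cbind(frequency_hz = 125 * 2^coords[, 1], level_db_hl = coords[, 2] * level_scale)
}

#' @export
print.tone_stimulus <- function(x, ...) {
  cat(sprintf("tone: %.5g Hz at %.4g dB HL\n", x$frequency_hz, x$level_db_hl))
  invisible(x)
}

#' GP hyperparameter bundles
#'
#' Constructors (with validity checks) for the three parameter bundles of the
#' tone-space classifier.
#'
#' * `kernel_params()`: squared-exponential (ARD) kernel, one lengthscale per
#'   scaled dimension. Defaults: signal variance 4 (prior latent sd 2),
#'   lengthscales 1 octave and 1 scaled level unit (= `level_scale` dB).
#' * `link_params()`: generalized logistic link `L / (1 + exp(-k (x - x0)))`;
#'   the default `L = 1, k = 1, x0 = 0` is the standard sigmoid and is what
#'   classification requires (outputs are probabilities).
#' * `mean_params()`: prior latent mean affine in scaled level,
#'   `offset + level_slope * (level - ref_level_db) / level_scale`. A positive
#'   slope encodes that louder tones are a priori more audible; the prior
#'   0.5-probability contour sits at `ref_level_db` (default 45 dB HL, the
#'   midpoint of the 10-80 dB HL dynamic range).
#'
#' @param signal_variance kernel signal variance (sigma_f^2), > 0.
#' @param lengthscale_freq lengthscale in octaves, > 0.
#' @param lengthscale_level lengthscale in scaled level units, > 0.
#' @return a validated list of class `"kernel_params"`, `"link_params"` or
#'   `"mean_params"`.
#' @export
kernel_params <- function(signal_variance = 4,
                          lengthscale_freq = 1,
                          lengthscale_level = 1) {
  vals <- c(signal_variance, lengthscale_freq, lengthscale_level)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("kernel parameters must all be strictly positive", call. = FALSE)
  }
  structure(
    list(
      signal_variance = signal_variance,
      lengthscale_freq = lengthscale_freq,
      lengthscale_level = lengthscale_level
    ),
    class = "kernel_params"
  )
}

#' @rdname kernel_params
#' @param max_value upper asymptote of the link (1 for a probability).
#' @param steepness logistic steepness k.
#' @param midpoint logistic midpoint x0.
#' @export
link_params <- function(max_value = 1, steepness = 1, midpoint = 0) {
  stopifnot(is.finite(max_value), is.finite(steepness), is.finite(midpoint))
  if (max_value <= 0 || max_value > 1) {
    stop("`max_value` must lie in (0, 1] for a probability link", call. = FALSE)
  }
  structure(
    list(max_value = max_value, steepness = steepness, midpoint = midpoint),
    class = "link_params"
  )
}

#' @rdname kernel_params
#' @param offset prior latent mean offset.
#' @param level_slope prior latent units per scaled level unit; must be >= 0
#'   (audibility is a priori non-decreasing in intensity).
#' @param ref_level_db level (dB HL) at which the prior latent mean equals
#'   `offset`.
#' @export
mean_params <- function(offset = 0, level_slope = 1, ref_level_db = 45) {
  stopifnot(is.finite(offset), is.finite(level_slope), is.finite(ref_level_db))
  if (level_slope < 0) {
    stop("`level_slope` must be >= 0", call. = FALSE)
  }
  structure(
    list(offset = offset, level_slope = level_slope, ref_level_db = ref_level_db),
    class = "mean_params"
  )
}

#' Squared-exponential covariance between tones
#'
#' ARD squared-exponential kernel on the scaled tone coordinates:
#' `sigma_f^2 * exp(-1/2 * sum_d (delta_d / l_d)^2)`. With equal lengthscales
#' this reduces to the isotropic kernel with a single characteristic
#' lengthscale.
#'
#' @param a,b `tone_stimulus` objects (or coordinate 2-vectors).
#' @param params a [kernel_params()] bundle.
#' @return scalar covariance, symmetric in its arguments and bounded by
#'   `signal_variance`.
#' @examples
#' a <- tone_stimulus(1000, 40); b <- tone_stimulus(2000, 60)
#' se_kernel(a, b, kernel_params())
#' @export
se_kernel <- function(a, b, params = kernel_params()) {
  if (!inherits(params, "kernel_params")) params <- do.call(kernel_params, params)
  ca <- if (inherits(a, "tone_stimulus")) a$coords else as.numeric(a)
  cb <- if (inherits(b, "tone_stimulus")) b$coords else as.numeric(b)
  d <- (as.numeric(ca) - as.numeric(cb)) /
    c(params$lengthscale_freq, params$lengthscale_level)
  params$signal_variance * exp(-0.5 * sum(d^2))
}

# Cross-covariance matrix between two coordinate matrices (n x 2, m x 2).
se_kernel_matrix <- function(ca, cb, params) {
  ls <- c(params$lengthscale_freq, params$lengthscale_level)
  a1 <- ca[, 1] / ls[1]; a2 <- ca[, 2] / ls[2]
  b1 <- cb[, 1] / ls[1]; b2 <- cb[, 2] / ls[2]
  d2 <- outer(a1, b1, "-")^2 + outer(a2, b2, "-")^2
  params$signal_variance * exp(-0.5 * d2)
}

#' Logistic link
#'
#' Generalized logistic `L / (1 + exp(-k (x - x0)))`, the standard sigmoid at
#' the default parameters. Saturates without overflow for large `|x|`.
#'
#' @param latent numeric vector of latent function values.
#' @param link a [link_params()] bundle.
#' @return probabilities in `[0, L]`.
#' @examples
#' logistic_link(0)    # 0.5
#' logistic_link(2)    # 0.8808
#' @export
logistic_link <- function(latent, link = link_params()) {
  link$max_value * stats::plogis(link$steepness * (latent - link$midpoint))
}

# Prior latent mean at coordinate matrix (n x 2), given the level scale used
# to build the coordinates.
prior_mean_at <- function(coords, mean, level_scale = 20) {
  unname(mean$offset + mean$level_slope *
           (coords[, 2] - mean$ref_level_db / level_scale))
}
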