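#' Sensor array on the follower surface
#'
#' An array of `n` sensor pairs, each indexed by one midline coordinate `s`
#' and expanding to two surface locations mirrored across the midline of the
#' frozen, straight follower (head at the origin, body along positive x).
#' Channel layout: channels `1..n` are the upper-side locations `x1(s_k)`,
#' channels `n+1..2n` the lower-side locations `x2(s_k)`. Duplicate `s`
#' values are permitted (the covariance floor keeps the matrix positive
#' definite).
#'
#' @param s Midline coordinates of the sensor pairs, all in `[0, s_max]`.
#' @param shape A [swimmer_shape()] providing the half-width offsets.
#' @param s_max Tail-exclusion cutoff; defaults to `0.95 * L`.
#' @return A tibble of class `sensor_array` with columns `s`, `x_upper`,
#'   `y_upper`, `x_lower`, `y_lower`.
#' @export
sensor_array <- function(s, shape, s_max = 0.95 * shape$L) {
  stopifnot(inherits(shape, "swimmer_shape"), length(s) >= 1)
  if (any(s < 0 | s > s_max + 1e-12)) {
    abort("sensor coordinates outside [0, s_max]")
  }
  w <- half_width(shape, s)
  out <- tibble(s = as.numeric(s),
                x_upper = as.numeric(s), y_upper = w,
                x_lower = as.numeric(s), y_lower = -w)
  class(out) <- c("sensor_array", class(out))
  attr(out, "shape") <- shape
  attr(out, "s_max") <- s_max
  out
}

#' Correlated measurement-noise model
#'
#' Exponentially decaying noise correlation along each body side:
#' `Sigma_ij = sigma^2 * exp(-d_ij / ell)` for channels on the same side
#' (`d_ij` the Euclidean distance of their surface locations) and 0 across
#' sides. For distinct channels whose surface distance satisfies
#' `d/ell < floor`, the exponential argument is floored at `floor`
#' (default `1e-7`), keeping off-diagonal entries strictly below `sigma^2`
#' so that the matrix stays positive definite even for duplicated sensors --
#' this is also what penalises excessive sensor clustering in the utility.
#'
#' @param sigma Noise scale (signal units); see [calibrate_sigma()].
#' @param ell Correlation length; the analyses use one tenth of the body
#'   length.
#' @param floor Lower bound on the exponential argument for distinct
#'   channels.
#' @return An object of class `covariance_model`.
#' @export
covariance_model <- function(sigma, ell, floor = 1e-7) {
  stopifnot(sigma > 0, ell > 0, floor > 0)
  structure(list(sigma = sigma, ell = ell, floor = floor),
            class = "covariance_model")
}

#' Calibrate the noise scale from forward signals
#'
#' Sets the noise scale to twice the mean absolute signal over channels and
#' prior samples: `sigma = (1 / (n * N_theta)) * sum_{j=1..2n} sum_i
#' |F(theta_i; s_j)|` (the sum over all `2n` channels divided by `n` equals
#' twice the per-channel mean).
#'
#' @param records A signal table ([generate_signal_table()]) or a single
#'   `signal_record`.
#' @param sensors A [sensor_array()].
#' @return The calibrated `sigma` (scalar).
#' @export
calibrate_sigma <- function(records, sensors) {
  f <- signals_at_sensors(records, sensors)
  if (!is.matrix(f)) f <- matrix(f, nrow = 1)
  n <- nrow(sensors)
  sigma <- sum(abs(f)) / (n * nrow(f))
  if (sigma <= 0) abort("all-zero signals: degenerate noise scale")
  sigma
}

#' Build the sensor-array covariance matrix
#'
#' @param sensors A [sensor_array()] with `n` sensor pairs.
#' @param cov A [covariance_model()].
#' @return A symmetric positive definite `2n` by `2n` matrix; block diagonal
#'   over the two sides.
#' @export
build_covariance <- function(sensors, cov) {
  stopifnot(inherits(sensors, "sensor_array"), inherits(cov, "covariance_model"))
  n <- nrow(sensors)
  block <- function(x, y) {
    d <- sqrt(outer(x, x, "-")^2 + outer(y, y, "-")^2)
    ratio <- d / cov$ell
    flo <- ratio < cov$floor & !diag(n)
    ratio[flo] <- cov$floor
    cov$sigma^2 * exp(-ratio)
  }
  Sigma <- matrix(0, 2 * n, 2 * n)
  Sigma[1:n, 1:n] <- block(sensors$x_upper, sensors$y_upper)
  Sigma[(n + 1):(2 * n), (n + 1):(2 * n)] <- block(sensors$x_lower,
                                                   sensors$y_lower)
  Sigma
}

# Cholesky with one jitter retry; returns the upper factor R (Sigma = R'R).
chol_safe <- function(Sigma, sigma2 = mean(diag(Sigma))) {
  R <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(R)) {
    message("covariance Cholesky failed; retrying with 1e-12 diagonal jitter")
    R <- tryCatch(chol(Sigma + diag(1e-12 * sigma2, nrow(Sigma))),
                  error = function(e) {
                    ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
                    abort(sprintf(
                      "covariance not positive definite (min eigenvalue %.3e)",
                      min(ev)))
                  })
  }
  R
}

#' Gaussian measurement log-likelihood
#'
#' Log-density of a measurement under the correlated Gaussian error model,
#' `log N(y | F, Sigma)`, evaluated through a Cholesky factorisation.
#'
#' @param y Measurement vector (length `2n`).
#' @param f Noise-free forward signal at the sensors (length `2n`).
#' @param Sigma Covariance matrix from [build_covariance()].
#' @return The log-density (scalar).
#' @export
log_likelihood <- function(y, f, Sigma) {
  if (length(y) != length(f) || length(y) != nrow(Sigma)) {
    abort("dimension mismatch between y, f and Sigma")
  }
  R <- chol_safe(Sigma)
  z <- forwardsolve(t(R), y - f)
  -0.5 * length(y) * log(2 * pi) - sum(log(diag(R))) - 0.5 * sum(z^2)
}
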