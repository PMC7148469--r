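#' Uniform prior over relative school positions
#'
#' Discretised uniform prior on a rectangle of relative positions of the
#' leading school (ahead-distance `x`, lateral offset `y`), the default
#' support being `[0.6, 0.8] x [0.1, 0.4]` on a 21 x 31 grid.
#'
#' @param xlim,ylim Rectangle bounds.
#' @param nx,ny Grid points per side.
#' @return A tibble with columns `theta_id`, `x`, `y`, `prior` (equal masses
#'   summing to 1).
#' @export
prior_position_grid <- function(xlim = c(0.6, 0.8), ylim = c(0.1, 0.4),
                                nx = 21, ny = 31) {
  g <- tidyr::expand_grid(x = seq(xlim[1], xlim[2], length.out = nx),
                          y = seq(ylim[1], ylim[2], length.out = ny))
  tibble(theta_id = seq_len(nrow(g)), x = g$x, y = g$y,
         prior = 1 / nrow(g))
}

#' Prior over school sizes
#'
#' Prior masses for the discrete school-size experiment. With
#' `weighting = "configuration"` every configuration of the catalogue has
#' equal mass, so size `i` receives `n_i / N_tot`; with `weighting = "size"`
#' all sizes are equally likely regardless of how many arrangements each one
#' has.
#'
#' @param catalogue A [configuration_catalogue()] tibble.
#' @param weighting `"configuration"` (default) or `"size"`.
#' @return A tibble with columns `size`, `n_config`, `prior`.
#' @export
prior_school_size <- function(catalogue,
                              weighting = c("configuration", "size")) {
  weighting <- match.arg(weighting)
  out <- dplyr::summarise(dplyr::group_by(catalogue, .data$size),
                          n_config = dplyr::n(), .groups = "drop")
  out$prior <- if (weighting == "configuration") {
    out$n_config / sum(out$n_config)
  } else {
    rep(1 / nrow(out), nrow(out))
  }
  out
}

#' Shannon entropy of a discrete distribution (nats)
#'
#' @param p Probability masses (normalised).
#' @return Entropy in nats.
#' @export
entropy_nats <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Kullback-Leibler divergence between two grid distributions
#'
#' `sum(q * log(q / p))` with the convention `0 * log 0 = 0`. Posterior mass
#' on cells of zero prior mass yields `+Inf` with a warning.
#'
#' @param q Posterior masses.
#' @param p Prior masses (same support, both normalised).
#' @return KL divergence in nats.
#' @export
kl_divergence_grid <- function(q, p) {
  stopifnot(length(q) == length(p))
  if (abs(sum(q) - 1) > 1e-8 || abs(sum(p) - 1) > 1e-8) {
    abort("both distributions must be normalised over the same support")
  }
  if (any(q > 0 & p == 0)) {
    warn("posterior mass outside the prior support: divergence is infinite")
    return(Inf)
  }
  i <- q > 0
  sum(q[i] * log(q[i] / p[i]))
}

# Whitened forward-signal matrix: rows f_i R^{-1} so that squared Euclidean
# distances become Mahalanobis distances under Sigma.
whiten_signals <- function(F_mat, Sigma) {
  R <- chol_safe(Sigma)
  t(forwardsolve(t(R), t(F_mat)))
}

new_utility_estimate <- function(estimate, se, Ntheta, Ny, seed) {
  structure(list(estimate = estimate, se = se, Ntheta = Ntheta, Ny = Ny,
                 seed = seed),
            class = "utility_estimate")
}

#' @export
print.utility_estimate <- function(x, ...) {
  cat(sprintf("<utility_estimate> %.4f nats (MC se %.4f; Ntheta=%d, Ny=%d)\n",
              x$estimate, x$se, x$Ntheta, x$Ny))
  invisible(x)
}

#' Expected information gain, continuous unknown
#'
#' Nested Monte Carlo estimator of the expected Kullback-Leibler divergence
#' between posterior and prior for a continuous unknown discretised on a
#' prior grid. The outer average runs over every prior sample (grid node)
#' with equal weight; for each sample, `Ny` synthetic measurements are drawn
#' from the Gaussian error model and the information gain per draw is
#' `log p(y | theta_i) - log mean_k p(y | theta_k)`. The inner
#' prior-predictive average uses the same forward signals, so no forward
#' evaluations beyond the `N_theta` records are needed. All likelihood
#' arithmetic is done in the log domain on whitened signals.
#'
#' @param signals A signal table from [generate_signal_table()] (one row per
#'   prior sample) or an `N_theta` by `2n` matrix of forward signals already
#'   interpolated at the sensors.
#' @param sensors A [sensor_array()] (ignored when `signals` is a matrix).
#' @param cov A [covariance_model()] or a precomputed covariance matrix.
#' @param Ny Synthetic measurements per prior sample.
#' @param seed Integer seed (common random numbers across designs are
#'   obtained by passing the same seed).
#' @return A `utility_estimate` with fields `estimate` (nats), `se` (Monte
#'   Carlo standard error), `Ntheta`, `Ny`, `seed`.
#' @export
expected_utility_continuous <- function(signals, sensors = NULL, cov,
                                        Ny = 1000, seed = NULL) {
  F_mat <- if (is.matrix(signals)) signals else signals_at_sensors(signals, sensors)
  if (nrow(F_mat) < 2) abort("need at least 2 prior samples")
  Sigma <- if (is.matrix(cov)) cov else build_covariance(sensors, cov)
  G <- whiten_signals(F_mat, Sigma)
  Nt <- nrow(G); d <- ncol(G)
  g2 <- rowSums(G^2)
  u <- numeric(Nt * Ny)
  with_seed(seed, {
    for (i in seq_len(Nt)) {
      Z <- matrix(rnorm(Ny * d), Ny, d)
      Y <- Z + matrix(G[i, ], Ny, d, byrow = TRUE)
      # -0.5 * squared distance of each draw to every whitened signal
      ll <- -0.5 * (rowSums(Y^2) + rep(g2, each = Ny) -
                      2 * Y %*% t(G))
      u[(i - 1) * Ny + seq_len(Ny)] <-
        -0.5 * rowSums(Z^2) - (row_logsumexp(ll) - log(Nt))
    }
  })
  new_utility_estimate(mean(u), sd(u) / sqrt(length(u)), Nt, Ny, seed)
}

#' Draw one measurement from a school-size mixture likelihood
#'
#' The likelihood of a school size is an equal-weight Gaussian mixture over
#' its catalogued arrangements. A draw picks an arrangement index uniformly,
#' then adds correlated Gaussian noise to that arrangement's signal.
#'
#' @param f_configs Matrix of the size's configuration signals at the
#'   sensors (one row per arrangement).
#' @param Sigma Covariance matrix.
#' @param seed Integer seed or `NULL`.
#' @return List with `y` (measurement vector) and `l` (the drawn arrangement
#'   index).
#' @export
sample_mixture_likelihood <- function(f_configs, Sigma, seed = NULL) {
  f_configs <- rbind(f_configs)
  if (nrow(f_configs) < 1) abort("empty configuration list")
  R <- chol_safe(Sigma)
  with_seed(seed, {
    l <- sample.int(nrow(f_configs), 1)
    z <- rnorm(ncol(f_configs))
    list(y = as.numeric(f_configs[l, ] + crossprod(R, z)), l = l)
  })
}

#' Log-likelihood of a school-size hypothesis (Gaussian mixture)
#'
#' `log( (1/n_i) * sum_l N(y | F(phi_il), Sigma) )`, computed with
#' log-sum-exp stabilisation.
#'
#' @param y Measurement vector.
#' @param f_configs Matrix of the size's configuration signals at the
#'   sensors (one row per arrangement).
#' @param Sigma Covariance matrix.
#' @return Scalar log-density.
#' @export
mixture_log_likelihood <- function(y, f_configs, Sigma) {
  f_configs <- rbind(f_configs)
  R <- chol_safe(Sigma)
  Gy <- as.numeric(forwardsolve(t(R), y))
  G <- t(forwardsolve(t(R), t(f_configs)))
  d2 <- rowSums((G - matrix(Gy, nrow(G), ncol(G), byrow = TRUE))^2)
  const <- -0.5 * length(y) * log(2 * pi) - sum(log(diag(R)))
  const + logsumexp(-0.5 * d2) - log(nrow(G))
}

#' Expected information gain, discrete unknown (school size)
#'
#' Monte Carlo estimator of the expected Kullback-Leibler utility when the
#' unknown is the school size and each size's likelihood is an equal-weight
#' Gaussian mixture over its catalogued arrangements. For each size `i`
#' (outer weight `p(theta_i)`) and each of `Ny` draws from its mixture, the
#' information gain is the mixture log-likelihood of the true size minus the
#' log of the prior-weighted mixture evidence.
#'
#' @param prior Tibble with columns `size` and `prior` (masses summing
#'   to 1), e.g. from [prior_school_size()].
#' @param signals A signal table carrying a `size` column (one row per
#'   catalogued arrangement), or a list with elements `F` (matrix of signals
#'   at sensors) and `size` (row group labels).
#' @param sensors,cov As in [expected_utility_continuous()].
#' @param Ny Draws per size.
#' @param seed Integer seed.
#' @return A `utility_estimate`.
#' @export
expected_utility_discrete <- function(prior, signals, sensors = NULL, cov,
                                      Ny = 1000, seed = NULL) {
  if (abs(sum(prior$prior) - 1) > 1e-8) abort("prior masses must sum to 1")
  if (is.list(signals) && !is.data.frame(signals) && !is.null(signals$F)) {
    F_mat <- signals$F; size_of_row <- signals$size
  } else {
    F_mat <- signals_at_sensors(signals, sensors)
    size_of_row <- signals$size
  }
  Sigma <- if (is.matrix(cov)) cov else build_covariance(sensors, cov)
  G <- whiten_signals(F_mat, Sigma)
  d <- ncol(G)
  sizes <- prior$size
  if (!all(sizes %in% size_of_row)) {
    abort("every size in the prior needs at least one configuration signal")
  }
  groups <- lapply(sizes, function(sz) which(size_of_row == sz))
  log_p <- log(prior$prior)
  log_ni <- log(vapply(groups, length, numeric(1)))

  gmat <- matrix(0, Ny, length(sizes))   # per-draw, per-true-size gains
  with_seed(seed, {
    for (ii in seq_along(sizes)) {
      rows <- groups[[ii]]
      lstar <- rows[sample.int(length(rows), Ny, replace = TRUE)]
      Z <- matrix(rnorm(Ny * d), Ny, d)
      Y <- G[lstar, , drop = FALSE] + Z
      # mixture log-likelihood of every size for every draw
      mix <- vapply(seq_along(sizes), function(mm) {
        Gm <- G[groups[[mm]], , drop = FALSE]
        ll <- -0.5 * (rowSums(Y^2) + rep(rowSums(Gm^2), each = Ny) -
                        2 * Y %*% t(Gm))
        row_logsumexp(ll) - log_ni[mm]
      }, numeric(Ny))
      evidence <- row_logsumexp(mix + matrix(log_p, Ny, length(sizes),
                                             byrow = TRUE))
      gmat[, ii] <- mix[, ii] - evidence
    }
  })
  per_draw <- as.numeric(gmat %*% prior$prior)
  new_utility_estimate(mean(per_draw), sd(per_draw) / sqrt(Ny),
                       length(sizes), Ny, seed)
}
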