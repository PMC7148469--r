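#' Utility functional for the relative-position experiment
#'
#' Packages prior signals, noise calibration and estimator settings into a
#' function of the sensor coordinates, the object consumed by
#' [place_sensors_sequential()]. The noise scale is calibrated once per
#' experiment from the forward signals on a dense reference grid (twice the
#' mean absolute signal), so comparing candidate designs does not change the
#' noise model.
#'
#' @param signal_tables A signal table, or a list of signal tables whose
#'   utilities are summed (the independent 1-, 4- and 7-leader
#'   sub-experiments of the relative-position study).
#' @param shape A [swimmer_shape()].
#' @param Ny Measurement draws per prior sample.
#' @param ell Noise correlation length, default one tenth of the body
#'   length.
#' @param sigma Noise scale; `NULL` calibrates per table with
#'   [calibrate_sigma()] on `n_ref` reference stations.
#' @param n_ref Reference stations used for calibration.
#' @return A function `f(s, seed)` returning a `utility_estimate` for sensor
#'   pairs at midline coordinates `s`.
#' @export
utility_functional_continuous <- function(signal_tables, shape, Ny = 1000,
                                          ell = 0.1 * shape$L, sigma = NULL,
                                          n_ref = 64) {
  if (is.data.frame(signal_tables)) signal_tables <- list(signal_tables)
  s_max <- 0.95 * shape$L
  ref <- sensor_array(seq(0, s_max, length.out = n_ref), shape)
  covs <- lapply(signal_tables, function(tab) {
    covariance_model(sigma %||% calibrate_sigma(tab, ref), ell)
  })
  function(s, seed = NULL) {
    sensors <- sensor_array(s, shape)
    parts <- purrr::map2(signal_tables, covs, function(tab, cv) {
      expected_utility_continuous(tab, sensors, cv, Ny = Ny, seed = seed)
    })
    est <- sum(vapply(parts, function(p) p$estimate, numeric(1)))
    se <- sqrt(sum(vapply(parts, function(p) p$se^2, numeric(1))))
    new_utility_estimate(est, se, parts[[1]]$Ntheta, Ny, seed)
  }
}

#' Utility functional for the school-size experiment
#'
#' @param prior Size prior from [prior_school_size()].
#' @param signal_table Catalogue signal table (with a `size` column).
#' @inheritParams utility_functional_continuous
#' @return A function `f(s, seed)` returning a `utility_estimate`.
#' @export
utility_functional_discrete <- function(prior, signal_table, shape,
                                        Ny = 1000, ell = 0.1 * shape$L,
                                        sigma = NULL, n_ref = 64) {
  s_max <- 0.95 * shape$L
  ref <- sensor_array(seq(0, s_max, length.out = n_ref), shape)
  cov <- covariance_model(sigma %||% calibrate_sigma(signal_table, ref), ell)
  function(s, seed = NULL) {
    sensors <- sensor_array(s, shape)
    expected_utility_discrete(prior, signal_table, sensors, cov,
                              Ny = Ny, seed = seed)
  }
}

#' Greedy sequential sensor placement
#'
#' Places `m` sensor pairs one after the other: with the first `k - 1`
#' optima fixed, the k-th coordinate is chosen by grid search over the
#' candidate stations, maximising the estimated expected utility of the
#' extended design. Within one step all candidates share the same random
#' seed (common random numbers, suppressing Monte Carlo noise in the
#' argmax); steps use fresh seeds. Ties are broken towards the smallest `s`.
#' Set `sense = "min"` to pick the worst location at each phase instead.
#'
#' @param utility_fn A function `f(s, seed) -> utility_estimate`, e.g. from
#'   [utility_functional_continuous()].
#' @param candidates Candidate midline stations (the default analyses use
#'   101 uniform stations on `[0, 0.95 L]`).
#' @param m Number of sensor pairs to place.
#' @param seed Integer seed.
#' @param sense `"max"` (optimal placement) or `"min"` (worst-case
#'   placement).
#' @return An object of class `sensor_placement`: list with `s_opt` (ordered
#'   chosen coordinates), `values`, `se` (utility and its MC standard error
#'   at each step) and `curves` (tibble `step`, `s`, `estimate`, `stderr`).
#' @export
place_sensors_sequential <- function(utility_fn, candidates, m, seed = 1,
                                     sense = c("max", "min")) {
  sense <- match.arg(sense)
  if (length(candidates) < 1) abort("candidate grid must be nonempty")
  chosen <- numeric(0)
  values <- numeric(0)
  ses <- numeric(0)
  curves <- vector("list", m)
  for (step in seq_len(m)) {
    step_seed <- seed + step
    ests <- purrr::map(candidates, function(sc) {
      utility_fn(c(chosen, sc), seed = step_seed)
    })
    est_vals <- vapply(ests, function(e) e$estimate, numeric(1))
    est_ses <- vapply(ests, function(e) e$se, numeric(1))
    best <- if (sense == "max") {
      order(-est_vals, candidates)[1]
    } else {
      order(est_vals, candidates)[1]
    }
    chosen <- c(chosen, candidates[best])
    values <- c(values, est_vals[best])
    ses <- c(ses, est_ses[best])
    curves[[step]] <- tibble(step = step, s = candidates,
                             estimate = est_vals, stderr = est_ses)
  }
  structure(list(s_opt = chosen, values = values, se = ses,
                 curves = dplyr::bind_rows(curves), sense = sense,
                 seed = seed),
            class = "sensor_placement")
}

#' @export
print.sensor_placement <- function(x, ...) {
  cat(sprintf("<sensor_placement> %d sensors (%s)\n", length(x$s_opt), x$sense))
  cat("  s* =", paste(signif(x$s_opt, 4), collapse = ", "), "\n")
  cat("  U  =", paste(signif(x$values, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Per-step utility increments and plateau detection
#'
#' Successive differences of the maximal expected utility along a sequential
#' placement. As sensors accumulate, the posterior approaches a point mass
#' and the expected utility saturates; the diagnostic flags saturation when
#' the increment stays below `tol` for `consecutive` consecutive steps.
#'
#' @param placement A `sensor_placement`.
#' @param tol Increment tolerance in nats.
#' @param consecutive Number of consecutive sub-tolerance increments
#'   required.
#' @return A tibble with columns `step`, `utility`, `increment`,
#'   `saturated`.
#' @export
plateau_diagnostic <- function(placement, tol = 0.01, consecutive = 3) {
  v <- placement$values
  if (length(v) < 2) abort("need at least 2 placement steps")
  inc <- c(NA_real_, diff(v))
  below <- !is.na(inc) & inc < tol
  runlen <- Reduce(function(acc, b) if (b) acc + 1L else 0L, below,
                   accumulate = TRUE)
  tibble(step = seq_along(v), utility = v, increment = inc,
         saturated = runlen >= consecutive)
}

#' Posterior over relative school positions
#'
#' Bayes' rule on the prior grid: mass proportional to likelihood times
#' prior, evaluated in the log domain and normalised.
#'
#' @param y Measurement vector (length `2n`, upper channels first).
#' @param sensors A [sensor_array()].
#' @param cov A [covariance_model()] or covariance matrix.
#' @param signals Signal table over the prior grid (columns `x`, `y`,
#'   `prior`, `signal`).
#' @return A tibble of class `posterior_grid` with columns `x`, `y`,
#'   `prior`, `posterior`.
#' @export
posterior_continuous <- function(y, sensors, cov, signals) {
  F_mat <- signals_at_sensors(signals, sensors)
  Sigma <- if (is.matrix(cov)) cov else build_covariance(sensors, cov)
  G <- whiten_signals(F_mat, Sigma)
  Gy <- as.numeric(forwardsolve(t(chol_safe(Sigma)), y))
  ll <- -0.5 * rowSums((G - matrix(Gy, nrow(G), ncol(G), byrow = TRUE))^2)
  lp <- ll + log(signals$prior)
  post <- exp(lp - logsumexp(lp))
  out <- tibble(x = signals$x, y = signals$y, prior = signals$prior,
                posterior = post / sum(post))
  class(out) <- c("posterior_grid", class(out))
  attr(out, "mode") <- c(out$x[which.max(post)], out$y[which.max(post)])
  attr(out, "support") <- "continuous"
  out
}

#' Posterior over school sizes
#'
#' Per-size posterior mass proportional to the size prior times the
#' equal-weight Gaussian mixture likelihood over that size's catalogued
#' arrangements.
#'
#' @param y Measurement vector.
#' @param sensors A [sensor_array()].
#' @param cov A [covariance_model()] or covariance matrix.
#' @param signals Catalogue signal table (columns `size`, `signal`).
#' @param prior Size prior from [prior_school_size()].
#' @return A tibble of class `posterior_grid` with columns `size`, `prior`,
#'   `posterior`.
#' @export
posterior_discrete <- function(y, sensors, cov, signals, prior) {
  F_mat <- signals_at_sensors(signals, sensors)
  Sigma <- if (is.matrix(cov)) cov else build_covariance(sensors, cov)
  mix <- vapply(prior$size, function(sz) {
    mixture_log_likelihood(y, F_mat[signals$size == sz, , drop = FALSE], Sigma)
  }, numeric(1))
  lp <- mix + log(prior$prior)
  post <- exp(lp - logsumexp(lp))
  out <- tibble(size = prior$size, prior = prior$prior,
                posterior = post / sum(post))
  class(out) <- c("posterior_grid", class(out))
  attr(out, "mode") <- prior$size[which.max(post)]
  attr(out, "support") <- "discrete"
  out
}
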