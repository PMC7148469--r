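# Independent quadrature oracles and small toy builders shared across tests.

# Expected information gain for a discrete prior over 1-channel Gaussian
# likelihoods, by direct trapezoid quadrature of the prior-predictive
# integral (no Monte Carlo).
oracle_eig_gaussian_1d <- function(means, sigma, p = NULL, ngrid = 20001) {
  p <- p %||% rep(1 / length(means), length(means))
  y <- seq(min(means) - 8 * sigma, max(means) + 8 * sigma, length.out = ngrid)
  dy <- y[2] - y[1]
  dens <- sapply(means, function(m) dnorm(y, m, sigma))
  ev <- as.numeric(dens %*% p)
  sum(vapply(seq_along(means), function(i) {
    p[i] * sum(dens[, i] * (dnorm(y, means[i], sigma, log = TRUE) - log(ev))) * dy
  }, numeric(1)))
}

# Same, for equal-weight Gaussian-mixture likelihoods (school sizes with
# several arrangements); f_list holds one vector of component means per size.
oracle_eig_mixture_1d <- function(f_list, sigma, p = NULL, ngrid = 40001) {
  p <- p %||% rep(1 / length(f_list), length(f_list))
  allf <- unlist(f_list)
  y <- seq(min(allf) - 8 * sigma, max(allf) + 8 * sigma, length.out = ngrid)
  dy <- y[2] - y[1]
  mix <- sapply(f_list, function(fs) {
    rowMeans(sapply(fs, function(m) dnorm(y, m, sigma)))
  })
  ev <- as.numeric(mix %*% p)
  sum(vapply(seq_along(f_list), function(i) {
    p[i] * sum(mix[, i] * (log(mix[, i]) - log(ev))) * dy
  }, numeric(1)))
}

# Two-channel version (independent unit-variance channels) on a tensor y
# grid; means is an N x 2 matrix. Used for the data-processing check.
oracle_eig_gaussian_2d <- function(means, ngrid = 281, span = 8) {
  N <- nrow(means)
  p <- rep(1 / N, N)
  y1 <- seq(min(means[, 1]) - span, max(means[, 1]) + span, length.out = ngrid)
  y2 <- seq(min(means[, 2]) - span, max(means[, 2]) + span, length.out = ngrid)
  dy <- (y1[2] - y1[1]) * (y2[2] - y2[1])
  U <- 0
  ll <- array(NA_real_, c(ngrid, ngrid, N))
  for (i in seq_len(N)) {
    ll[, , i] <- outer(dnorm(y1, means[i, 1], log = TRUE),
                       dnorm(y2, means[i, 2], log = TRUE), "+")
  }
  lev <- apply(ll, c(1, 2), function(v) {
    m <- max(v); m + log(mean(exp(v - m)))
  })
  for (i in seq_len(N)) {
    U <- U + p[i] * sum(exp(ll[, , i]) * (ll[, , i] - lev)) * dy
  }
  U
}

# Small random discrete sensing problem (signals given directly at sensors).
random_discrete_problem <- function(seed, n_channels = 2) {
  set.seed(seed)
  n_sizes <- sample(2:4, 1)
  n_cfg <- sample(1:3, n_sizes, replace = TRUE)
  F_mat <- matrix(rnorm(sum(n_cfg) * n_channels, sd = runif(1, 0.5, 3)),
                  ncol = n_channels)
  size_of_row <- rep(seq_len(n_sizes), n_cfg)
  pr <- runif(n_sizes); pr <- pr / sum(pr)
  Sigma <- diag(runif(1, 0.3, 2)^2, n_channels)
  list(prior = tibble::tibble(size = seq_len(n_sizes), prior = pr),
       signals = list(F = F_mat, size = size_of_row),
       Sigma = Sigma)
}

# A fabricated noise-free signal record with prescribed constant side values.
constant_record <- function(upper, lower, L = 0.1,
                            s = seq(0, 0.95 * L, length.out = 33)) {
  rec <- tibble::tibble(s = s, upper = rep(upper, length(s)),
                        lower = rep(lower, length(s)))
  class(rec) <- c("signal_record", class(rec))
  attr(rec, "type") <- "test"
  rec
}

toy_shape <- function() swimmer_shape()
toy_model <- function(...) surrogate_model(...)

`%||%` <- function(a, b) if (is.null(a)) b else a
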