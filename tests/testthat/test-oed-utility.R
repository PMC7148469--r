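test_that("priors are normalised with the documented supports", {
  pg <- prior_position_grid()
  expect_equal(nrow(pg), 21 * 31)
  expect_equal(sum(pg$prior), 1)
  expect_equal(range(pg$x), c(0.6, 0.8))
  expect_equal(range(pg$y), c(0.1, 0.4))
  cat61 <- configuration_catalogue()
  ps <- prior_school_size(cat61)
  expect_equal(ps$prior, ps$n_config / 61)
  ps2 <- prior_school_size(cat61, weighting = "size")
  expect_equal(ps2$prior, rep(1 / 8, 8))
})

test_that("KL divergence on grids follows the closed forms", {
  p <- rep(1 / 5, 5)
  expect_equal(kl_divergence_grid(p, p), 0)
  q <- c(1, 0, 0, 0, 0)
  expect_equal(kl_divergence_grid(q, p), log(5))
  q3 <- c(0.5, 0.3, 0.2); p3 <- c(0.2, 0.5, 0.3)
  expect_equal(kl_divergence_grid(q3, p3),
               0.5 * log(0.5 / 0.2) + 0.3 * log(0.3 / 0.5) + 0.2 * log(0.2 / 0.3))
  expect_warning(val <- kl_divergence_grid(c(0.5, 0.5, 0), c(0.5, 0, 0.5)),
                 "infinite")
  expect_identical(val, Inf)
})

test_that("continuous estimator matches nested quadrature on the linear toy", {
  theta <- seq(0, 1, length.out = 21)
  sigma <- 0.05
  oracle <- oracle_eig_gaussian_1d(theta, sigma)
  est <- expected_utility_continuous(matrix(theta, ncol = 1),
                                     cov = matrix(sigma^2, 1, 1),
                                     Ny = 500, seed = 7)
  expect_lt(abs(est$estimate - oracle), 3 * est$se)
  expect_gt(est$se, 0)
})

test_that("continuous estimator hits the no-information and saturation limits", {
  # identical signals for every prior sample: zero expected gain
  F0 <- matrix(0.3, 11, 2)
  est0 <- expected_utility_continuous(F0, cov = diag(0.2, 2), Ny = 300, seed = 1)
  expect_lt(abs(est0$estimate), 3 * max(est0$se, 1e-12))
  # widely separated signals: prior entropy ceiling ln(Ntheta)
  Fw <- matrix(seq(0, 40, length.out = 8), ncol = 1)
  estw <- expected_utility_continuous(Fw, cov = matrix(1e-4, 1, 1),
                                      Ny = 200, seed = 2)
  expect_equal(estw$estimate, log(8), tolerance = 1e-6)
  expect_error(expected_utility_continuous(matrix(1, 1, 1),
                                           cov = matrix(1, 1, 1), Ny = 10),
               "at least 2")
})

test_that("mixture sampling draws components uniformly and collapses correctly", {
  f <- rbind(c(0, 0), c(5, 5), c(-5, 2))
  S <- diag(0.25, 2)
  draws <- with_seed_draws <- vapply(1:3000, function(i) {
    sample_mixture_likelihood(f, S)$l
  }, numeric(1))
  freq <- tabulate(draws, 3) / 3000
  expect_true(all(abs(freq - 1 / 3) < 3 * sqrt((1 / 3) * (2 / 3) / 3000)))
  # single component: plain Gaussian about that signal
  set.seed(10)
  y1 <- sample_mixture_likelihood(f[1, , drop = FALSE], S)$y
  expect_equal(length(y1), 2)
  # vanishing noise returns one of the component signals exactly
  y0 <- sample_mixture_likelihood(f, diag(1e-30, 2), seed = 3)$y
  expect_true(any(apply(f, 1, function(r) isTRUE(all.equal(r, y0, tolerance = 1e-9)))))
})

test_that("mixture log-likelihood matches direct summation", {
  S <- matrix(c(0.5, 0.1, 0.1, 0.3), 2, 2)
  f <- rbind(c(0.2, -0.1), c(1, 0.4), c(-0.5, 0.9))
  y <- c(0.3, 0.2)
  direct <- log(mean(vapply(1:3, function(l) {
    exp(log_likelihood(y, f[l, ], S))
  }, numeric(1))))
  expect_equal(mixture_log_likelihood(y, f, S), direct, tolerance = 1e-12)
  # one component reduces to the plain log-likelihood
  expect_equal(mixture_log_likelihood(y, f[2, , drop = FALSE], S),
               log_likelihood(y, f[2, ], S))
  # duplicated components collapse to the single-component value
  expect_equal(mixture_log_likelihood(y, rbind(f[1, ], f[1, ]), S),
               log_likelihood(y, f[1, ], S), tolerance = 1e-12)
})

test_that("discrete estimator matches quadrature and its separable limit", {
  sigma <- 0.2
  f_list <- list(c(0, 0.3), c(0.6, 1.1))
  oracle <- oracle_eig_mixture_1d(f_list, sigma)
  prior <- tibble::tibble(size = 1:2, prior = c(0.5, 0.5))
  sig <- list(F = matrix(unlist(f_list), ncol = 1), size = c(1, 1, 2, 2))
  est <- expected_utility_discrete(prior, sig, cov = matrix(sigma^2, 1, 1),
                                   Ny = 3000, seed = 3)
  expect_lt(abs(est$estimate - oracle), 3 * est$se + 2e-3)
  # 100-sigma separation: ln 2 to high precision
  sep <- list(F = matrix(c(0, 100 * sigma), ncol = 1), size = 1:2)
  est2 <- expected_utility_discrete(prior, sep, cov = matrix(sigma^2, 1, 1),
                                    Ny = 500, seed = 4)
  expect_equal(est2$estimate, log(2), tolerance = 1e-6)
  # all sizes sharing one signal carry no information
  same <- list(F = matrix(0.7, 3, 1), size = c(1, 2, 2))
  est3 <- expected_utility_discrete(tibble::tibble(size = 1:2, prior = c(0.4, 0.6)),
                                    same, cov = matrix(0.1, 1, 1),
                                    Ny = 400, seed = 5)
  expect_lt(abs(est3$estimate), 3 * max(est3$se, 1e-12))
  expect_error(
    expected_utility_discrete(tibble::tibble(size = 1:2, prior = c(0.7, 0.7)),
                              same, cov = matrix(0.1, 1, 1), Ny = 10),
    "sum to 1")
})

test_that("estimates respect information bounds and are seed-deterministic", {
  for (seed in 1:6) {
    prob <- random_discrete_problem(seed)
    est <- expected_utility_discrete(prob$prior, prob$signals,
                                     cov = prob$Sigma, Ny = 300, seed = seed)
    H <- entropy_nats(prob$prior$prior)
    expect_gte(est$estimate, -3 * est$se)
    expect_lte(est$estimate, H + 3 * est$se)
    est_again <- expected_utility_discrete(prob$prior, prob$signals,
                                           cov = prob$Sigma, Ny = 300,
                                           seed = seed)
    expect_identical(est$estimate, est_again$estimate)
  }
  theta <- seq(-1, 1, length.out = 9)
  e1 <- expected_utility_continuous(matrix(theta, ncol = 1),
                                    cov = matrix(0.09, 1, 1), Ny = 150, seed = 5)
  e2 <- expected_utility_continuous(matrix(theta, ncol = 1),
                                    cov = matrix(0.09, 1, 1), Ny = 150, seed = 5)
  expect_identical(e1$estimate, e2$estimate)
  expect_gte(e1$estimate, -3 * e1$se)
  expect_lte(e1$estimate, log(9) + 3 * e1$se)
})

test_that("reported standard error shrinks like one over sqrt(samples)", {
  theta <- seq(0, 1, length.out = 11)
  ses <- vapply(c(50, 500, 5000), function(ny) {
    expected_utility_continuous(matrix(theta, ncol = 1),
                                cov = matrix(0.04, 1, 1),
                                Ny = ny, seed = 1)$se
  }, numeric(1))
  slope <- coef(lm(log(ses) ~ log(c(50, 500, 5000) * 11)))[2]
  expect_gt(slope, -0.65)
  expect_lt(slope, -0.35)
})

test_that("adding a channel never decreases the quadrature utility", {
  theta <- seq(0, 2, length.out = 7)
  u1 <- oracle_eig_gaussian_1d(theta, 1)
  # second channel carries an independent reading of the same unknown
  u2 <- oracle_eig_gaussian_2d(cbind(theta, 0.5 * theta), ngrid = 241)
  expect_gte(u2, u1 - 1e-3)
  # and a pure-noise second channel leaves the utility unchanged
  u2n <- oracle_eig_gaussian_2d(cbind(theta, 0), ngrid = 241)
  expect_equal(u2n, u1, tolerance = 5e-3)
})
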