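test_that("spline pressure-gradient extraction is exact for polynomials of the null space", {
  s <- seq(0, 1, length.out = 101)
  expect_equal(smooth_pressure_gradient(s, rep(2.5, 101))$value,
               rep(0, 101))
  expect_equal(smooth_pressure_gradient(s, 3 * s)$value, rep(3, 101),
               tolerance = 1e-8)
  expect_error(smooth_pressure_gradient(s[1:3], s[1:3]), "at least 4")
  expect_error(smooth_pressure_gradient(c(0, 0.5, 0.2, 1), 1:4), "increasing")
})

test_that("spline smoothing recovers a quadratic gradient from noisy samples", {
  set.seed(202)
  s <- seq(0, 1, length.out = 201)
  p <- s^2 + rnorm(201, sd = 1e-3)
  g <- smooth_pressure_gradient(s, p)
  interior <- s >= 0.1 & s <= 0.9
  expect_lt(max(abs(g$value[interior] - 2 * s[interior])), 0.1)
})

test_that("two-point shear estimate is exact for linear profiles, O(h) otherwise", {
  nu <- 1e-3
  expect_equal(shear_from_velocity(0, 0, 0.01, 0.02, nu), 0)
  gam <- 2.4
  expect_equal(shear_from_velocity(gam * 0.01, gam * 0.02, 0.01, 0.02, nu),
               nu * gam)
  # quadratic profile u = n^2 sampled at h and 2h: the difference quotient
  # gives 3h, so the wall-shear bias is exactly nu * 3h
  h <- 0.005
  expect_equal(shear_from_velocity(h^2, (2 * h)^2, h, 2 * h, nu), nu * 3 * h)
  expect_error(shear_from_velocity(1, 2, 0.01, 0.01, nu), "spacing")
})

test_that("mirror-symmetric schools induce identical signals on both sides", {
  sh <- toy_shape()
  mod <- toy_model()
  on_axis <- school_configuration("continuous", r = c(0.7, 0))
  for (type in c("pressure_gradient", "shear", "pressure")) {
    rec <- generate_signal(mod, on_axis, sh, type = type)
    expect_equal(rec$upper, rec$lower, tolerance = 1e-12)
    expect_true(all(is.finite(rec$upper)))
  }
  # symmetric three-leader wedge, still symmetric about the axis
  wedge <- school_configuration("continuous", r = c(0.7, 0),
                                offsets = cbind(c(-0.1, 0.05, 0.05),
                                                c(0, 0.15, -0.15)))
  rec <- generate_signal(mod, wedge, sh)
  expect_equal(rec$upper, rec$lower, tolerance = 1e-12)
  # off-axis school breaks the symmetry
  off <- generate_signal(mod, school_configuration("continuous", r = c(0.7, 0.25)), sh)
  expect_gt(max(abs(off$upper - off$lower)), 0)
})

test_that("signals superpose linearly in the leader strengths", {
  sh <- toy_shape()
  cfg <- school_configuration("continuous", r = c(0.7, 0.2),
                              offsets = canonical_offsets(3))
  m1 <- surrogate_model(mu = 1e-3, wake_gamma = 2e-3)
  m2 <- surrogate_model(mu = 2e-3, wake_gamma = 4e-3)
  r1 <- generate_signal(m1, cfg, sh)
  r2 <- generate_signal(m2, cfg, sh)
  expect_equal(r2$upper, 2 * r1$upper, tolerance = 1e-12)
  expect_equal(r2$lower, 2 * r1$lower, tolerance = 1e-12)
})

test_that("signal amplitude decays monotonically with leader distance", {
  sh <- toy_shape()
  # dipole-only model probed at sub-body-length distances
  mod0 <- surrogate_model(n_wake = 0)
  amp0 <- vapply(c(0.02, 0.04, 0.08), function(d) {
    max(abs(signals_at_sensors(
      generate_signal(mod0, school_configuration("continuous", r = c(d, 0)), sh),
      sensor_array(seq(0, 0.09, length.out = 12), sh))))
  }, numeric(1))
  expect_true(all(diff(amp0) < 0))
  # full model with wake, probed across the prior range of ahead distances
  mod <- toy_model()
  amp <- vapply(c(0.45, 0.65, 0.85), function(d) {
    max(abs(signals_at_sensors(
      generate_signal(mod, school_configuration("continuous", r = c(d, 0)), sh),
      sensor_array(seq(0, 0.09, length.out = 12), sh))))
  }, numeric(1))
  expect_true(all(diff(amp) < 0))
})

test_that("tail exclusion and singularity collisions are enforced", {
  sh <- toy_shape()
  mod <- toy_model()
  cfg <- school_configuration("continuous", r = c(0.7, 0.2))
  expect_error(generate_signal(mod, cfg, sh, s_grid = seq(0, sh$L, length.out = 11)),
               "tail-exclusion")
  expect_error(sensor_array(0.98 * sh$L, sh), "s_max")
  # a leader sitting exactly on a surface point is rejected
  s0 <- 0.05
  bad <- school_configuration("continuous", r = c(-s0, half_width(sh, s0)))
  expect_error(generate_signal(mod, bad, sh,
                               s_grid = seq(0, 0.09, length.out = 19)),
               "coincides")
})

test_that("the configuration catalogue enumerates 61 distinct equal-mass arrangements", {
  cat61 <- configuration_catalogue()
  expect_equal(nrow(cat61), 61)
  expect_equal(unique(cat61$size), 1:8)
  expect_equal(dplyr::count(cat61, size)$n, c(1, 2, 4, 6, 9, 11, 13, 15))
  expect_equal(sum(cat61$prior), 1)
  expect_equal(unique(cat61$prior), 1 / 61)
  # arrangements are centred and pairwise distinct
  keys <- vapply(cat61$offsets, function(m) {
    expect_equal(colMeans(m), c(0, 0), tolerance = 1e-12)
    m <- m[order(round(m[, 1], 9), round(m[, 2], 9)), , drop = FALSE]
    paste(sprintf("%.8f %.8f", m[, 1], m[, 2]), collapse = ";")
  }, character(1))
  expect_equal(anyDuplicated(keys), 0L)
  # lattice spacing: nearest-neighbour distances are multiples of the spacing
  off5 <- cat61$offsets[[which(cat61$size == 5)[1]]]
  d <- as.matrix(dist(off5))
  expect_gte(min(d[d > 0]), 0.15 - 1e-9)
  # size 1 admits exactly one arrangement
  expect_equal(configuration_catalogue(sizes = 1, counts = 1)$offsets[[1]],
               matrix(0, 1, 2), ignore_attr = TRUE)
})

test_that("sampled measurements have the advertised mean and covariance", {
  sh <- toy_shape()
  mod <- toy_model()
  rec <- generate_signal(mod, school_configuration("continuous", r = c(0.7, 0.25)), sh)
  sens <- sensor_array(c(0.01, 0.04), sh)
  f <- signals_at_sensors(rec, sens)
  cv <- covariance_model(sigma = 2e-4, ell = 0.01)
  Sigma <- build_covariance(sens, cv)
  n_draw <- 10000
  Y <- with(list(), {
    set.seed(99)
    t(vapply(seq_len(n_draw), function(i) sample_measurement(rec, sens, Sigma),
             numeric(4)))
  })
  se_mean <- sqrt(diag(Sigma) / n_draw)
  expect_true(all(abs(colMeans(Y) - f) < 3 * se_mean))
  emp <- cov(Y)
  se_cov <- sqrt((outer(diag(Sigma), diag(Sigma)) + Sigma^2) / n_draw)
  expect_true(all(abs(emp - Sigma) < 3.5 * se_cov))
  # zero-noise limit returns the interpolated signal exactly
  y0 <- sample_measurement(rec, sens, diag(1e-30, 4), seed = 1)
  expect_equal(y0, as.numeric(f), tolerance = 1e-9)
  expect_error(sample_measurement(rec, sensor_array(0.094, sh), diag(1e-8, 2)),
               NA)
})

test_that("identical seeds reproduce signals and measurements bit for bit", {
  sh <- toy_shape()
  mod <- toy_model()
  cfg <- school_configuration("continuous", r = c(0.66, 0.3))
  r1 <- generate_signal(mod, cfg, sh)
  r2 <- generate_signal(mod, cfg, sh)
  expect_identical(r1$upper, r2$upper)
  sens <- sensor_array(c(0, 0.03), sh)
  S <- build_covariance(sens, covariance_model(1e-4, 0.01))
  expect_identical(sample_measurement(r1, sens, S, seed = 5),
                   sample_measurement(r1, sens, S, seed = 5))
})

test_that("signal variance profile matches a direct two-pass computation", {
  sh <- toy_shape()
  mod <- toy_model()
  grid5 <- prior_position_grid(nx = 3, ny = 2)
  tab <- generate_signal_table(mod, grid5, sh, nf = 1)
  sv <- signal_variance(tab)
  up <- do.call(rbind, lapply(tab$signal, function(r) r$upper))
  direct <- apply(up, 2, function(col) sum((col - mean(col))^2) / (length(col) - 1))
  expect_equal(sv$variance[sv$side == "upper"], direct)
  # identical records have zero variance
  tab0 <- tab
  tab0$signal <- rep(tab$signal[1], nrow(tab))
  expect_equal(max(signal_variance(tab0)$variance), 0)
  # two records differing by a constant c on one side: variance c^2 / 2
  recA <- constant_record(1, 0)
  recB <- constant_record(1 + 0.4, 0)
  tab2 <- tibble::tibble(id = 1:2, signal = list(recA, recB))
  sv2 <- signal_variance(tab2)
  expect_equal(unique(sv2$variance[sv2$side == "upper"]), 0.4^2 / 2)
  expect_equal(unique(sv2$variance[sv2$side == "lower"]), 0)
  expect_error(signal_variance(tab2[1, ]), "at least 2")
})
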