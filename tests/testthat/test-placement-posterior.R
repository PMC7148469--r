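# Shared small continuous problem: 1 leader, coarse prior grid.
make_position_problem <- function(nx = 7, ny = 7, Ny = 120) {
  sh <- toy_shape()
  mod <- toy_model()
  tab <- generate_signal_table(mod, prior_position_grid(nx = nx, ny = ny),
                               sh, nf = 1)
  fn <- utility_functional_continuous(tab, sh, Ny = Ny)
  ref <- sensor_array(seq(0, 0.095, length.out = 64), sh)
  cv <- covariance_model(calibrate_sigma(tab, ref), 0.01)
  list(shape = sh, model = mod, tab = tab, fn = fn, cov = cv)
}

test_that("a single sensor is placed at the argmax of its utility curve", {
  prob <- make_position_problem()
  cand <- seq(0, 0.09, length.out = 7)
  pl <- place_sensors_sequential(prob$fn, cand, m = 1, seed = 3)
  curve <- pl$curves
  expect_equal(pl$s_opt, curve$s[which.max(curve$estimate)])
  expect_equal(pl$values, max(curve$estimate))
  expect_error(place_sensors_sequential(prob$fn, numeric(0), 1), "nonempty")
})

test_that("greedy placement matches exhaustive joint search on a small toy", {
  prob <- make_position_problem()
  cand <- seq(0, 0.09, length.out = 5)
  seed <- 11
  pl <- place_sensors_sequential(prob$fn, cand, m = 2, seed = seed)
  # exhaustive 25-evaluation joint oracle under the second step's seed
  joint <- expand.grid(s1 = cand, s2 = cand)
  joint$u <- vapply(seq_len(nrow(joint)), function(i) {
    prob$fn(c(joint$s1[i], joint$s2[i]), seed = seed + 2)$estimate
  }, numeric(1))
  best_joint <- max(joint$u)
  greedy_u <- pl$values[2]
  se <- prob$fn(pl$s_opt, seed = seed + 2)$se
  # greedy can only fall short of the joint optimum, and by no more than
  # Monte Carlo noise on this separable toy
  expect_lte(greedy_u, best_joint + 3 * se)
  expect_gte(greedy_u, best_joint - 6 * se)
})

test_that("the covariance floor steers the second sensor away from the first", {
  prob <- make_position_problem()
  cand <- seq(0, 0.09, length.out = 5)
  pl <- place_sensors_sequential(prob$fn, cand, m = 3, seed = 2)
  expect_equal(length(unique(pl$s_opt)), 3)
  # utilities never decrease along the greedy sequence
  expect_true(all(diff(pl$values) > -3 * max(pl$se)))
})

test_that("worst-case placement selects the per-phase argmin", {
  prob <- make_position_problem()
  cand <- seq(0, 0.09, length.out = 5)
  worst <- place_sensors_sequential(prob$fn, cand, m = 1, seed = 2,
                                    sense = "min")
  curve <- worst$curves
  expect_equal(worst$s_opt, curve$s[which.min(curve$estimate)])
})

test_that("continuous posterior obeys Bayes' rule on the grid", {
  prob <- make_position_problem()
  sens <- sensor_array(c(0, 0.02, 0.05), prob$shape)
  Sigma <- build_covariance(sens, prob$cov)
  true_i <- 25
  y <- signals_at_sensors(prob$tab$signal[[true_i]], sens)
  post <- posterior_continuous(y, sens, Sigma, prob$tab)
  expect_equal(sum(post$posterior), 1, tolerance = 1e-12)
  expect_true(all(post$posterior >= 0))
  expect_equal(which.max(post$posterior), true_i)
  expect_equal(attr(post, "mode"), c(prob$tab$x[true_i], prob$tab$y[true_i]))
  # flat likelihood returns the prior
  tab_flat <- prob$tab
  tab_flat$signal <- rep(tab_flat$signal[1], nrow(tab_flat))
  post_flat <- posterior_continuous(y, sens, Sigma, tab_flat)
  expect_equal(post_flat$posterior, post_flat$prior, tolerance = 1e-9)
})

test_that("discrete posterior recovers the size and degrades gracefully", {
  sh <- toy_shape()
  mod <- toy_model()
  cat3 <- configuration_catalogue(sizes = 1:3, counts = c(1, 2, 2))
  tab <- generate_signal_table(mod, cat3, sh)
  prior <- prior_school_size(cat3)
  sens <- sensor_array(c(0, 0.03), sh)
  ref <- sensor_array(seq(0, 0.095, length.out = 64), sh)
  cv <- covariance_model(calibrate_sigma(tab, ref), 0.01)
  Sigma <- build_covariance(sens, cv)
  y <- signals_at_sensors(tab$signal[[which(tab$size == 2)[1]]], sens)
  post <- posterior_discrete(y, sens, Sigma, tab, prior)
  expect_equal(sum(post$posterior), 1, tolerance = 1e-12)
  expect_equal(post$size[which.max(post$posterior)], 2)
  # single size in the prior: all mass on it
  post1 <- posterior_discrete(y, sens, Sigma, tab[tab$size == 2, ],
                              prior_school_size(cat3[cat3$size == 2, ]))
  expect_equal(post1$posterior, 1)
  # near-identical signals across sizes: posterior entropy within 1% of prior
  tab_deg <- tab
  base <- tab$signal[[1]]
  tab_deg$signal <- lapply(seq_len(nrow(tab)), function(i) {
    r <- base
    r$upper <- r$upper * (1 + 1e-9 * i)
    r
  })
  post_deg <- posterior_discrete(signals_at_sensors(base, sens), sens, Sigma,
                                 tab_deg, prior)
  expect_gt(entropy_nats(post_deg$posterior),
            0.99 * entropy_nats(prior$prior))
})

test_that("coasting snapshots identify the school size; richer catalogues blur it", {
  sh <- toy_shape()
  mod <- toy_model()
  ref <- sensor_array(seq(0, 0.095, length.out = 64), sh)
  sens <- sensor_array(0.003, sh)
  # one arrangement per size: every size recovered exactly
  cat1 <- configuration_catalogue(counts = rep(1, 8))
  tab1 <- generate_signal_table(mod, cat1, sh)
  pr1 <- prior_school_size(cat1)
  S1 <- build_covariance(sens, covariance_model(calibrate_sigma(tab1, ref),
                                                0.1 * sh$L))
  mass1 <- numeric(8)
  for (sz in 1:8) {
    y <- signals_at_sensors(tab1$signal[[which(tab1$size == sz)]], sens)
    post <- posterior_discrete(y, sens, S1, tab1, pr1)
    expect_equal(post$size[which.max(post$posterior)], sz)
    mass1[sz] <- post$posterior[post$size == sz]
  }
  # the full multi-arrangement catalogue is less informative about the truth
  cat61 <- configuration_catalogue()
  tab61 <- generate_signal_table(mod, cat61, sh)
  pr61 <- prior_school_size(cat61)
  S61 <- build_covariance(sens, covariance_model(calibrate_sigma(tab61, ref),
                                                 0.1 * sh$L))
  y2 <- signals_at_sensors(tab61$signal[[which(tab61$size == 2)[1]]], sens)
  post61 <- posterior_discrete(y2, sens, S61, tab61, pr61)
  expect_lt(post61$posterior[post61$size == 2], mass1[2])
})

test_that("plateau diagnostic flags saturation after a Dirac posterior", {
  fake <- structure(list(values = c(1, 1.5, 1.7, 1.703, 1.705, 1.706),
                         s_opt = 1:6, se = rep(0.001, 6), sense = "max"),
                    class = "sensor_placement")
  pd <- plateau_diagnostic(fake, tol = 0.01)
  expect_equal(pd$increment[-1], diff(fake$values))
  expect_false(any(pd$saturated[1:4]))
  expect_true(pd$saturated[6])
  const <- structure(list(values = rep(2, 4), s_opt = 1:4,
                          se = rep(0, 4), sense = "max"),
                     class = "sensor_placement")
  expect_equal(plateau_diagnostic(const)$increment[-1], rep(0, 3))
  expect_error(plateau_diagnostic(structure(list(values = 1),
                                            class = "sensor_placement")),
               "at least 2")
})

test_that("tidiers and plots expose placement and posterior summaries", {
  prob <- make_position_problem(nx = 4, ny = 4, Ny = 60)
  cand <- seq(0, 0.09, length.out = 4)
  pl <- place_sensors_sequential(prob$fn, cand, m = 2, seed = 1)
  td <- tidy(pl)
  expect_equal(nrow(td), 2)
  expect_named(td, c("step", "s", "utility", "std.error"))
  gl <- glance(pl)
  expect_equal(gl$n_sensors, 2)
  expect_s3_class(autoplot(pl), "ggplot")
  sens <- sensor_array(pl$s_opt, prob$shape)
  Sigma <- build_covariance(sens, prob$cov)
  y <- signals_at_sensors(prob$tab$signal[[3]], sens)
  post <- posterior_continuous(y, sens, Sigma, prob$tab)
  expect_s3_class(autoplot(post), "ggplot")
  expect_named(glance(post), c("mode_x", "mode_y", "entropy", "kl_from_prior"))
  expect_s3_class(autoplot(prob$tab$signal[[1]]), "ggplot")
})
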