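#' Run a full sensor-placement experiment
#'
#' End-to-end orchestration of one of the two sensing studies on the
#' synthetic surrogate: forward signals over the prior support, noise
#' calibration, greedy sequential placement (optimal and worst designs),
#' plateau diagnostic and posterior inference demonstrations. The
#' relative-position study runs independent sub-experiments with 1, 4 and 7
#' leaders and maximises the sum of their expected utilities.
#'
#' @param config A named list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{experiment}{`"school-size"` or `"relative-position"`.}
#'     \item{seed}{Integer seed (default 1).}
#'     \item{m_sensors}{Sensors to place (default 3).}
#'     \item{Ny}{Measurement draws per prior sample (default 200).}
#'     \item{n_candidates}{Candidate stations for the grid search
#'       (default 101).}
#'     \item{type}{`"pressure_gradient"` (default) or `"shear"`.}
#'     \item{sub_sizes}{Leader counts of the relative-position
#'       sub-experiments (default `c(1, 4, 7)`).}
#'     \item{r0}{School centre of mass for the school-size study
#'       (default `c(0.7, 0.25)`).}
#'     \item{counts}{Catalogue counts per size (default
#'       `c(1, 2, 4, 6, 9, 11, 13, 15)`).}
#'     \item{prior}{Continuous prior settings (`xlim`, `ylim`, `nx`, `ny`).}
#'     \item{surrogate}{Arguments forwarded to [surrogate_model()].}
#'     \item{out_dir}{If set, CSV/JSON archive written there.}
#'   }
#' @return An object of class `school_experiment`: list with the placements
#'   (`optimal`, `worst`), `plateau`, `sigma`, `posteriors` (noise-free
#'   recovery demonstrations at the optimal and worst designs) and
#'   `config`.
#' @export
run_experiment <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  experiment <- match.arg(config$experiment, c("school-size", "relative-position"))
  seed <- config$seed %||% 1L
  m <- config$m_sensors %||% 3L
  Ny <- config$Ny %||% 200L
  n_cand <- config$n_candidates %||% 101L
  type <- config$type %||% "pressure_gradient"
  shape <- swimmer_shape()
  model <- do.call(surrogate_model, config$surrogate %||% list())
  s_max <- 0.95 * shape$L
  candidates <- seq(0, s_max, length.out = n_cand)

  if (experiment == "school-size") {
    catalogue <- configuration_catalogue(counts = config$counts %||%
                                           c(1, 2, 4, 6, 9, 11, 13, 15))
    tab <- generate_signal_table(model, catalogue, shape,
                                 r0 = config$r0 %||% c(0.7, 0.25),
                                 type = type)
    prior <- prior_school_size(catalogue)
    fn <- utility_functional_discrete(prior, tab, shape, Ny = Ny)
    ref <- sensor_array(seq(0, s_max, length.out = 64), shape)
    sigma <- calibrate_sigma(tab, ref)
    cov <- covariance_model(sigma, 0.1 * shape$L)

    optimal <- place_sensors_sequential(fn, candidates, m, seed = seed)
    worst <- place_sensors_sequential(fn, candidates, m, seed = seed,
                                      sense = "min")
    # noise-free recovery demonstration: y = F(first arrangement of each size)
    posteriors <- purrr::map(prior$size, function(sz) {
      rec <- tab$signal[[which(tab$size == sz)[1]]]
      purrr::map(list(optimal = optimal$s_opt, worst = worst$s_opt),
                 function(sv) {
                   sens <- sensor_array(sv, shape)
                   posterior_discrete(signals_at_sensors(rec, sens),
                                      sens, cov, tab, prior)
                 })
    })
    names(posteriors) <- paste0("size_", prior$size)
    tables <- list(catalogue = tab)
  } else {
    prior_cfg <- config$prior %||% list()
    prior <- prior_position_grid(xlim = prior_cfg$xlim %||% c(0.6, 0.8),
                                 ylim = prior_cfg$ylim %||% c(0.1, 0.4),
                                 nx = prior_cfg$nx %||% 21,
                                 ny = prior_cfg$ny %||% 31)
    sub_sizes <- config$sub_sizes %||% c(1, 4, 7)
    tabs <- purrr::map(sub_sizes, function(nf) {
      generate_signal_table(model, prior, shape, nf = nf, type = type)
    })
    names(tabs) <- paste0("nf_", sub_sizes)
    fn <- utility_functional_continuous(tabs, shape, Ny = Ny)
    ref <- sensor_array(seq(0, s_max, length.out = 64), shape)
    sigma <- vapply(tabs, function(tb) calibrate_sigma(tb, ref), numeric(1))

    optimal <- place_sensors_sequential(fn, candidates, m, seed = seed)
    worst <- place_sensors_sequential(fn, candidates, m, seed = seed,
                                      sense = "min")
    true_node <- which.min((prior$x - mean(prior$x))^2 +
                             (prior$y - mean(prior$y))^2)
    posteriors <- purrr::imap(tabs, function(tb, nm) {
      cv <- covariance_model(sigma[[nm]], 0.1 * shape$L)
      rec <- tb$signal[[true_node]]
      purrr::map(list(optimal = optimal$s_opt, worst = worst$s_opt),
                 function(sv) {
                   sens <- sensor_array(sv, shape)
                   posterior_continuous(signals_at_sensors(rec, sens),
                                        sens, cv, tb)
                 })
    })
    tables <- tabs
  }

  out <- structure(list(
    experiment = experiment,
    optimal = optimal, worst = worst,
    plateau = if (m >= 2) plateau_diagnostic(optimal) else NULL,
    sigma = sigma,
    posteriors = posteriors,
    tables = tables,
    config = list(seed = seed, m_sensors = m, Ny = Ny,
                  n_candidates = n_cand, type = type)
  ), class = "school_experiment")

  if (!is.null(config$out_dir)) write_experiment(out, config$out_dir)
  out
}

#' @export
print.school_experiment <- function(x, ...) {
  cat(sprintf("<school_experiment> %s\n", x$experiment))
  cat("  optimal sensors:", paste(signif(x$optimal$s_opt, 4), collapse = ", "),
      "\n")
  cat("  utility at optimum:", signif(x$optimal$values[length(x$optimal$values)], 4),
      "nats\n")
  invisible(x)
}

#' Write a plain-text archive of an experiment
#'
#' Utility curves and chosen designs as CSV, calibration and provenance as
#' JSON.
#'
#' @param x A `school_experiment`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(x$optimal$curves,
                   file.path(dir, "utility_curves_optimal.csv"),
                   row.names = FALSE)
  utils::write.csv(tidy(x$optimal), file.path(dir, "placement_optimal.csv"),
                   row.names = FALSE)
  utils::write.csv(tidy(x$worst), file.path(dir, "placement_worst.csv"),
                   row.names = FALSE)
  if (!is.null(x$plateau)) {
    utils::write.csv(x$plateau, file.path(dir, "plateau.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    list(experiment = x$experiment, sigma = x$sigma, config = x$config,
         package_version = as.character(utils::packageVersion("schoolsense"))),
    file.path(dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
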