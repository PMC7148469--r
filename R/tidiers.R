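#' @export
tidy.utility_estimate <- function(x, ...) {
  tibble(estimate = x$estimate, std.error = x$se,
         n_theta = x$Ntheta, n_y = x$Ny)
}

#' Tidy a sequential placement: one row per placed sensor
#' @param x A `sensor_placement`.
#' @param ... Unused.
#' @export
tidy.sensor_placement <- function(x, ...) {
  tibble(step = seq_along(x$s_opt), s = x$s_opt,
         utility = x$values, std.error = x$se)
}

#' @export
glance.sensor_placement <- function(x, ...) {
  pd <- if (length(x$s_opt) >= 2) plateau_diagnostic(x) else NULL
  tibble(n_sensors = length(x$s_opt),
         utility = x$values[length(x$values)],
         saturated = if (is.null(pd)) NA else any(pd$saturated),
         sense = x$sense)
}

#' @export
tidy.posterior_grid <- function(x, ...) as_tibble(x)

#' @export
glance.posterior_grid <- function(x, ...) {
  kl <- kl_divergence_grid(x$posterior, x$prior)
  if (attr(x, "support") == "continuous") {
    tibble(mode_x = attr(x, "mode")[1], mode_y = attr(x, "mode")[2],
           entropy = entropy_nats(x$posterior), kl_from_prior = kl)
  } else {
    tibble(mode_size = attr(x, "mode"),
           entropy = entropy_nats(x$posterior), kl_from_prior = kl)
  }
}

#' Plot the per-step utility curves of a sequential placement
#' @param object A `sensor_placement`.
#' @param ... Unused.
#' @export
autoplot.sensor_placement <- function(object, ...) {
  picked <- tidy(object)
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(x = .data$s, y = .data$estimate,
                               colour = factor(.data$step))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = picked,
                        ggplot2::aes(x = .data$s, y = .data$utility,
                                     colour = factor(.data$step)),
                        size = 2) +
    ggplot2::labs(x = "midline coordinate s", y = "expected utility (nats)",
                  colour = "sensor")
}

#' Plot a posterior distribution over the prior support
#' @param object A `posterior_grid`.
#' @param ... Unused.
#' @export
autoplot.posterior_grid <- function(object, ...) {
  if (attr(object, "support") == "continuous") {
    ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y,
                                         fill = .data$posterior)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_viridis_c() +
      ggplot2::labs(x = "ahead distance", y = "lateral offset")
  } else {
    ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$size),
                                         y = .data$posterior)) +
      ggplot2::geom_col() +
      ggplot2::labs(x = "school size", y = "posterior mass")
  }
}
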