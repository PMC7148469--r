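#' Potential-flow surrogate for leading-school surface signals
#'
#' Stand-in forward model for the surface signals a frozen follower measures
#' in the wake of a leading school. Each leader contributes a potential-flow
#' dipole (order `decay_exponent`, oriented along the swimming axis) plus a
#' short trailing wake of counter-rotating point-vortex pairs with alternating
#' circulation, so the induced field is a linear superposition over leaders,
#' decays with distance, oscillates along the wake, and is mirror-symmetric
#' whenever the school configuration is. Pressure follows from the Bernoulli
#' relation linearised about the coasting cruise stream, `p = -U0 * u_x`
#' (unit density; `u_x` the streamwise perturbation velocity), so every
#' signal is exactly linear in the leader strengths; the pressure gradient
#' is the exact tangential derivative along the surface, and shear is a
#' boundary-layer scaling `nu * u_t / bl_thickness` of the
#' surface-tangential velocity.
#'
#' The surrogate reproduces the statistical structure the design analysis
#' assumes (smoothness in `s`, injectivity over the prior support, symmetry,
#' distance decay); it is not a high-Reynolds wake model.
#'
#' @param mu Dipole strength per leader (length^2 / time for the default
#'   order 1).
#' @param decay_exponent Order of the dipole-like pole; the potential decays
#'   as `1/d^decay_exponent`, the velocity one power faster.
#' @param wake_wavelength Streamwise spacing of successive wake vortex pairs.
#' @param wake_gamma Circulation magnitude of the first vortex pair.
#' @param wake_width Half-spacing of each counter-rotating pair.
#' @param wake_decay Geometric decay of circulation along the wake.
#' @param n_wake Number of vortex pairs per leader.
#' @param cruise_speed Coasting speed `U0` of the follower relative to the
#'   ambient water, used by the linearised pressure relation (default one
#'   body length per tail-beat period).
#' @param bl_thickness Boundary-layer thickness used by the shear scaling.
#' @param nu Kinematic viscosity used by the shear scaling.
#' @return An object of class `surrogate_model`.
#' @export
surrogate_model <- function(mu = 1e-3, decay_exponent = 1,
                            wake_wavelength = 0.1, wake_gamma = 2e-3,
                            wake_width = 0.02, wake_decay = 0.7, n_wake = 3,
                            cruise_speed = 0.1, bl_thickness = 0.001,
                            nu = 5e-6) {
  stopifnot(mu > 0, decay_exponent >= 1, wake_wavelength > 0,
            wake_width > 0, n_wake >= 0, cruise_speed > 0, bl_thickness > 0,
            nu > 0)
  structure(list(mu = mu, decay_exponent = decay_exponent,
                 wake_wavelength = wake_wavelength, wake_gamma = wake_gamma,
                 wake_width = wake_width, wake_decay = wake_decay,
                 n_wake = n_wake, cruise_speed = cruise_speed,
                 bl_thickness = bl_thickness, nu = nu),
            class = "surrogate_model")
}

#' School configuration (the unknown of the sensing problem)
#'
#' Describes one hypothesis about the leading school: its relative position
#' and/or its size together with a concrete leader arrangement. The follower
#' is frozen straight with its head at the origin and body along positive x;
#' the school centre of mass sits at `(-r[1], r[2])` relative to the head
#' (`r[1]` body ahead-distance, `r[2]` lateral offset, both in domain units).
#'
#' @param mode `"continuous"` (unknown relative position `r`) or
#'   `"discrete"` (unknown school size `nf`).
#' @param r Relative position `(x, y)` of the school centre of mass.
#' @param nf Number of leaders.
#' @param offsets `nf` by 2 matrix of leader positions relative to the school
#'   centre of mass (centroid zero).
#' @param label Configuration label, e.g. `"3.2"` for the second arrangement
#'   of a three-leader school.
#' @return An object of class `school_configuration`.
#' @export
school_configuration <- function(mode = c("continuous", "discrete"),
                                 r = c(0.7, 0.25), nf = NULL,
                                 offsets = NULL, label = NULL) {
  mode <- match.arg(mode)
  if (is.null(offsets)) offsets <- matrix(0, 1, 2)
  offsets <- as.matrix(offsets)
  stopifnot(ncol(offsets) == 2)
  if (is.null(nf)) nf <- nrow(offsets)
  stopifnot(nf == nrow(offsets))
  if (anyDuplicated(round(offsets, 12))) {
    abort("leader placements must be pairwise distinct")
  }
  structure(list(mode = mode, r = as.numeric(r), nf = nf,
                 offsets = offsets, label = label %||% sprintf("%d.1", nf)),
            class = "school_configuration")
}

#' Deterministic catalogue of staggered school arrangements
#'
#' Enumerates, for each school size, a fixed number of distinct leader
#' arrangements on a staggered lattice with spacing `spacing` in both
#' directions. Arrangements are windows in a canonical ordering of lattice
#' sites (sorted by distance from the school centre, then angle), re-centred
#' so each arrangement's centroid is the school centre of mass; duplicates
#' under this re-centring are skipped deterministically. Every configuration
#' carries equal prior mass `1/sum(counts)`.
#'
#' The per-size counts default to `c(1, 2, 4, 6, 9, 11, 13, 15)` for sizes
#' 1 to 8, i.e. 61 configurations in total.
#'
#' @param sizes School sizes to enumerate.
#' @param counts Number of arrangements per size (same length as `sizes`).
#' @param spacing Lattice spacing in x and y.
#' @return A tibble with columns `size`, `config` (index within size),
#'   `label`, `offsets` (list-column of matrices) and `prior`.
#' @export
configuration_catalogue <- function(sizes = 1:8,
                                    counts = c(1, 2, 4, 6, 9, 11, 13, 15),
                                    spacing = 0.15) {
  stopifnot(length(sizes) == length(counts), all(counts >= 1), spacing > 0)
  # canonical staggered lattice: columns offset by half a spacing
  cols <- 0:6
  rows <- -4:4
  sites <- expand.grid(col = cols, row = rows)
  sx <- sites$col * spacing
  sy <- (sites$row + (sites$col %% 2) / 2) * spacing
  ord <- order(round(sqrt(sx^2 + sy^2), 9), round(atan2(sy, sx), 9))
  sx <- sx[ord]; sy <- sy[ord]
  n_tot <- sum(counts)

  canon_key <- function(m) {
    m <- sweep(m, 2, colMeans(m))
    m <- m[order(round(m[, 1], 9), round(m[, 2], 9)), , drop = FALSE]
    paste(sprintf("%.9f,%.9f", m[, 1], m[, 2]), collapse = ";")
  }

  rows_out <- list()
  for (k in seq_along(sizes)) {
    nf <- sizes[k]
    seen <- character(0)
    found <- 0L
    l <- 1L
    while (found < counts[k]) {
      idx <- l:(l + nf - 1)
      if (max(idx) > length(sx)) {
        abort("lattice too small for the requested catalogue")
      }
      m <- cbind(sx[idx], sy[idx])
      key <- canon_key(m)
      if (!key %in% seen) {
        seen <- c(seen, key)
        found <- found + 1L
        off <- sweep(m, 2, colMeans(m))
        rows_out[[length(rows_out) + 1L]] <- tibble(
          size = nf, config = found,
          label = sprintf("%d.%d", nf, found),
          offsets = list(off), prior = 1 / n_tot
        )
      }
      l <- l + 1L
    }
  }
  dplyr::bind_rows(rows_out)
}

# Complex velocity (u + i v) of the surrogate singularity system at points z.
surrogate_velocity <- function(model, config, z, deriv = 0) {
  com <- complex(real = -config$r[1], imaginary = config$r[2])
  leaders <- com + complex(real = config$offsets[, 1],
                           imaginary = config$offsets[, 2])
  q <- model$decay_exponent
  Wp <- rep(0 + 0i, length(z))
  Wpp <- rep(0 + 0i, length(z))
  for (z0 in leaders) {
    dz <- z - z0
    Wp <- Wp - q * model$mu / dz^(q + 1)
    if (deriv > 0) Wpp <- Wpp + q * (q + 1) * model$mu / dz^(q + 2)
    if (model$n_wake > 0) {
      for (m in seq_len(model$n_wake)) {
        gam <- model$wake_gamma * (-1)^(m - 1) * model$wake_decay^(m - 1)
        zu <- z0 + m * model$wake_wavelength + 1i * model$wake_width
        zl <- z0 + m * model$wake_wavelength - 1i * model$wake_width
        Wp <- Wp - 1i * gam / (2 * pi * (z - zu)) +
          1i * gam / (2 * pi * (z - zl))
        if (deriv > 0) {
          Wpp <- Wpp + 1i * gam / (2 * pi * (z - zu)^2) -
            1i * gam / (2 * pi * (z - zl)^2)
        }
      }
    }
  }
  list(Wp = Wp, Wpp = Wpp,
       singularities = c(leaders,
                         unlist(lapply(leaders, function(z0) {
                           if (model$n_wake == 0) return(complex(0))
                           m <- seq_len(model$n_wake)
                           c(z0 + m * model$wake_wavelength + 1i * model$wake_width,
                             z0 + m * model$wake_wavelength - 1i * model$wake_width)
                         }))))
}

#' Generate a noise-free surface signal record
#'
#' Evaluates the surrogate flow of a school configuration on the two surface
#' sides of the frozen, straight follower body and reduces it to the
#' requested sensor quantity: the tangential pressure gradient along the
#' surface, the wall shear stress, or the raw surface pressure.
#'
#' @param model A [surrogate_model()].
#' @param config A [school_configuration()].
#' @param shape A [swimmer_shape()].
#' @param s_grid Midline stations; must satisfy `max(s_grid) <= 0.95 L` (tail
#'   exclusion). Default: 121 stations on `[0, 0.95 L]`.
#' @param type `"pressure_gradient"`, `"shear"` or `"pressure"`.
#' @return A tibble of class `signal_record` with columns `s`, `upper`,
#'   `lower` and attributes `type` and `config`.
#' @export
generate_signal <- function(model, config, shape,
                            s_grid = seq(0, 0.95 * shape$L, length.out = 121),
                            type = c("pressure_gradient", "shear", "pressure")) {
  type <- match.arg(type)
  stopifnot(inherits(model, "surrogate_model"),
            inherits(config, "school_configuration"),
            inherits(shape, "swimmer_shape"))
  s_max <- 0.95 * shape$L
  if (any(s_grid < 0 | s_grid > s_max + 1e-12)) {
    abort("s_grid outside the tail-exclusion range [0, 0.95 L]")
  }
  w <- half_width(shape, s_grid)
  # tangential direction of the upper surface: (1, w'(s)) normalised
  eps <- 1e-7 * shape$L
  wp <- (half_width(shape, pmin(s_grid + eps, shape$L)) -
           half_width(shape, pmax(s_grid - eps, 0))) /
    (pmin(s_grid + eps, shape$L) - pmax(s_grid - eps, 0))
  tn <- sqrt(1 + wp^2)

  one_side <- function(sign_side) {
    z <- complex(real = s_grid, imaginary = sign_side * w)
    tt <- complex(real = 1, imaginary = sign_side * wp) / tn
    fv <- surrogate_velocity(model, config, z, deriv = 1)
    if (min(Mod(outer(z, fv$singularities, "-"))) < 1e-9) {
      abort("a leader or wake vortex coincides with a surface point")
    }
    switch(type,
      pressure = -model$cruise_speed * Re(fv$Wp),
      pressure_gradient = -model$cruise_speed * Re(fv$Wpp * tt),
      shear = model$nu * Re(Conj(fv$Wp) * Conj(tt)) / model$bl_thickness
    )
  }
  out <- tibble(s = s_grid, upper = one_side(1), lower = one_side(-1))
  class(out) <- c("signal_record", class(out))
  attr(out, "type") <- type
  attr(out, "config") <- config
  out
}

#' Forward-signal table over a set of configurations
#'
#' Maps [generate_signal()] over the rows of a configuration table and stores
#' each record in a list-column, the tidy container consumed by the utility
#' estimators and posterior functions.
#'
#' @param model A [surrogate_model()].
#' @param configs Either a tibble from [configuration_catalogue()] (discrete
#'   experiment; leaders are placed around `r0`) or a tibble with columns `x`,
#'   `y` from [prior_position_grid()] (continuous experiment; `nf` leaders in
#'   the canonical arrangement are placed around each grid node).
#' @param shape A [swimmer_shape()].
#' @param r0 School centre of mass used for the discrete experiment.
#' @param nf Number of leaders used for the continuous experiment.
#' @param s_grid,type Passed to [generate_signal()].
#' @return The input tibble with an added list-column `signal`.
#' @export
generate_signal_table <- function(model, configs, shape, r0 = c(0.7, 0.25),
                                  nf = 1,
                                  s_grid = seq(0, 0.95 * shape$L, length.out = 121),
                                  type = "pressure_gradient") {
  if ("offsets" %in% names(configs)) {
    configs$signal <- purrr::map(seq_len(nrow(configs)), function(i) {
      cfg <- school_configuration("discrete", r = r0,
                                  offsets = configs$offsets[[i]],
                                  label = configs$label[i])
      generate_signal(model, cfg, shape, s_grid, type)
    })
  } else {
    stopifnot(all(c("x", "y") %in% names(configs)))
    off <- canonical_offsets(nf)
    configs$signal <- purrr::map(seq_len(nrow(configs)), function(i) {
      cfg <- school_configuration("continuous",
                                  r = c(configs$x[i], configs$y[i]),
                                  offsets = off)
      generate_signal(model, cfg, shape, s_grid, type)
    })
  }
  configs
}

#' Canonical leader arrangement of a given size
#'
#' First catalogue arrangement for size `nf`: the window of the canonical
#' staggered-lattice ordering, centred on the school centre of mass.
#'
#' @param nf Number of leaders.
#' @param spacing Lattice spacing.
#' @return `nf` by 2 offset matrix.
#' @export
canonical_offsets <- function(nf, spacing = 0.15) {
  cat <- configuration_catalogue(sizes = nf, counts = 1, spacing = spacing)
  cat$offsets[[1]]
}

#' Pressure-gradient extraction by spline smoothing
#'
#' Fits a smoothing spline to surface pressure samples along the midline
#' coordinate and returns its derivative: the tangential pressure gradient a
#' canal-neuromast-like sensor reads. For noise-free constant or linear
#' pressure the result is exact (the penalty null space of a cubic smoothing
#' spline is the linear functions).
#'
#' @param s Monotone increasing midline coordinates (at least 4).
#' @param pressure Pressure samples at `s`.
#' @param s_out Evaluation grid for the gradient (default `s`).
#' @param spar Optional smoothing parameter forwarded to
#'   [stats::smooth.spline()]; default generalised cross-validation.
#' @return A tibble with columns `s` and `value` (signal type
#'   `"pressure_gradient"` in the `type` attribute).
#' @export
smooth_pressure_gradient <- function(s, pressure, s_out = s, spar = NULL) {
  if (length(s) < 4) abort("need at least 4 pressure samples")
  if (is.unsorted(s, strictly = TRUE)) abort("s must be strictly increasing")
  stopifnot(length(pressure) == length(s))
  if (max(pressure) - min(pressure) < .Machine$double.eps * 100) {
    out <- tibble(s = s_out, value = rep(0, length(s_out)))
  } else {
    fit <- if (is.null(spar)) {
      smooth.spline(s, pressure)
    } else {
      smooth.spline(s, pressure, spar = spar)
    }
    out <- tibble(s = s_out, value = predict(fit, s_out, deriv = 1)$y)
  }
  attr(out, "type") <- "pressure_gradient"
  out
}

#' Wall shear stress from near-wall tangential velocities
#'
#' One-sided finite-difference estimate of `nu * d(u_t)/dn` at a no-slip
#' surface from the tangential velocity at the two nearest grid points along
#' the wall normal: `nu * (ut2 - ut1) / (n2 - n1)`. Exact for a linear shear
#' layer; first-order (O(h)) biased for curved profiles.
#'
#' @param ut1,ut2 Tangential velocities at wall-normal distances `n1 < n2`.
#' @param n1,n2 Wall-normal distances of the two sample points.
#' @param nu Kinematic viscosity.
#' @return Shear stress estimates (unit density).
#' @export
shear_from_velocity <- function(ut1, ut2, n1, n2, nu) {
  if (any(n2 - n1 <= 0) || any(n1 <= 0)) {
    abort("sample points must be ordered by wall distance with nonzero spacing")
  }
  nu * (ut2 - ut1) / (n2 - n1)
}

#' Draw a noisy sensor measurement from a signal record
#'
#' Interpolates the noise-free record at the sensor stations (cubic spline
#' per side) and adds one zero-mean Gaussian draw with the sensor-array
#' covariance: `y = F(theta; s) + eps`, `eps ~ N(0, Sigma(s))`.
#'
#' @param record A `signal_record` from [generate_signal()].
#' @param sensors A [sensor_array()].
#' @param cov A [covariance_model()] (or a precomputed 2n x 2n covariance
#'   matrix).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return Numeric measurement vector of length `2n` (upper channels first).
#' @export
sample_measurement <- function(record, sensors, cov, seed = NULL) {
  f <- signals_at_sensors(record, sensors)
  Sigma <- if (is.matrix(cov)) cov else build_covariance(sensors, cov)
  R <- chol(Sigma)
  with_seed(seed, {
    z <- rnorm(length(f))
    as.numeric(f + crossprod(R, z))
  })
}

#' Interpolate signal records at sensor stations
#'
#' @param records A single `signal_record` or a signal table from
#'   [generate_signal_table()].
#' @param sensors A [sensor_array()].
#' @return For a single record, a length-`2n` vector (upper side first); for
#'   a table, an `N` by `2n` matrix with one row per record.
#' @export
signals_at_sensors <- function(records, sensors) {
  interp_one <- function(rec) {
    rng <- range(rec$s)
    if (any(sensors$s < rng[1] - 1e-12 | sensors$s > rng[2] + 1e-12)) {
      abort("sensor location outside the recorded s range")
    }
    up <- splinefun(rec$s, rec$upper)(sensors$s)
    lo <- splinefun(rec$s, rec$lower)(sensors$s)
    c(up, lo)
  }
  if (inherits(records, "signal_record")) {
    interp_one(records)
  } else if (is.data.frame(records) && "signal" %in% names(records)) {
    do.call(rbind, purrr::map(records$signal, interp_one))
  } else {
    abort("records must be a signal_record or a signal table")
  }
}

#' Signal variance profile across configurations
#'
#' Per-station, per-side sample variance of the noise-free signals across the
#' configurations of a signal table: the diagnostic that links preferred
#' sensor locations to locations of large signal variability.
#'
#' @param records A signal table from [generate_signal_table()] (at least 2
#'   rows); all records must share one `s` grid.
#' @param denominator `"unbiased"` (divide by `N - 1`, default) or
#'   `"biased"` (divide by `N`).
#' @return A tibble with columns `s`, `side`, `variance`.
#' @export
signal_variance <- function(records, denominator = c("unbiased", "biased")) {
  denominator <- match.arg(denominator)
  if (!is.data.frame(records) || !"signal" %in% names(records) ||
      nrow(records) < 2) {
    abort("need a signal table with at least 2 records")
  }
  s <- records$signal[[1]]$s
  up <- do.call(rbind, purrr::map(records$signal, "upper"))
  lo <- do.call(rbind, purrr::map(records$signal, "lower"))
  vfun <- function(m) {
    v <- apply(m, 2, var)
    if (denominator == "biased") v <- v * (nrow(m) - 1) / nrow(m)
    v
  }
  dplyr::bind_rows(
    tibble(s = s, side = "upper", variance = vfun(up)),
    tibble(s = s, side = "lower", variance = vfun(lo))
  )
}

#' @export
autoplot.signal_record <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), c("upper", "lower"),
                              names_to = "side", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$s, y = .data$value,
                                     colour = .data$side)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "midline coordinate s", y = attr(object, "type"))
}
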