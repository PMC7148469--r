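#' Slender-body swimmer shape
#'
#' A fish-like body of length `L` is described by its half-width `w(s)` along
#' the midline coordinate `s` (head at `s = 0`, tail at `s = L`). The profile
#' has three pieces: an elliptic head `sqrt(2*wh*s - s^2)` up to `sb`, a linear
#' taper from `wh` down to `wt` between `sb` and `st`, and a linear tail
#' vanishing at `s = L`. With the default parameters
#' (`wh = sb = 0.04 L`, `st = 0.95 L`, `wt = 0.01 L`) the profile is
#' continuous at both breakpoints.
#'
#' The head piece is taken as `sqrt(2*wh*s - s^2)`, the unique reading that is
#' continuous with the middle piece at `sb` when `sb = wh`.
#'
#' @param L Body length (simulation length units).
#' @param wh Head half-width.
#' @param sb,st Shape breakpoints along the midline, `0 < sb < st < L`.
#' @param wt Tail half-width at `st`.
#' @return An object of class `swimmer_shape`.
#' @examples
#' sh <- swimmer_shape()
#' half_width(sh, c(0, sh$sb, sh$st, sh$L))
#' @export
swimmer_shape <- function(L = 0.1, wh = 0.04 * L, sb = 0.04 * L,
                          st = 0.95 * L, wt = 0.01 * L) {
  stopifnot(L > 0, sb > 0, sb < st, st < L, wt > 0, wt < wh)
  if (sb > 2 * wh) {
    abort("head piece requires sb <= 2*wh so that 2*wh*s - s^2 >= 0 on [0, sb]")
  }
  structure(list(L = L, wh = wh, sb = sb, st = st, wt = wt),
            class = "swimmer_shape")
}

#' @export
print.swimmer_shape <- function(x, ...) {
  cat(sprintf("<swimmer_shape> L=%g wh=%g sb=%g st=%g wt=%g\n",
              x$L, x$wh, x$sb, x$st, x$wt))
  invisible(x)
}

#' Half-width profile of the swimmer body
#'
#' Evaluates the piecewise half-width `w(s)` of a [swimmer_shape()].
#'
#' @param shape A [swimmer_shape()].
#' @param s Midline coordinates in `[0, L]` (vectorised).
#' @return Half-widths, same length as `s`.
#' @export
half_width <- function(shape, s) {
  stopifnot(inherits(shape, "swimmer_shape"))
  if (any(s < 0 | s > shape$L)) {
    abort("midline coordinate s outside [0, L]")
  }
  w <- numeric(length(s))
  head_i <- s < shape$sb
  mid_i <- s >= shape$sb & s < shape$st
  tail_i <- s >= shape$st
  w[head_i] <- sqrt(pmax(2 * shape$wh * s[head_i] - s[head_i]^2, 0))
  w[mid_i] <- shape$wh - (shape$wh - shape$wt) *
    (s[mid_i] - shape$sb) / (shape$st - shape$sb)
  w[tail_i] <- shape$wt * (shape$L - s[tail_i]) / (shape$L - shape$st)
  w
}

#' Anguilliform midline kinematics
#'
#' Travelling curvature wave `k(s, t) = A(s) sin(2*pi*t/Tp - 2*pi*s/L)` with a
#' linearly increasing amplitude envelope from `A0` at the head to `AL` at the
#' tail, replicating eel-like (anguilliform) swimming.
#'
#' @param L Body length.
#' @param Tp Tail-beat period (time units).
#' @param A0,AL Curvature amplitude (1/length) at head and tail.
#' @return An object of class `midline_kinematics`.
#' @export
midline_kinematics <- function(L = 0.1, Tp = 1, A0 = 0.82 / L, AL = 5.7 / L) {
  stopifnot(L > 0, Tp > 0)
  structure(list(L = L, Tp = Tp, A0 = A0, AL = AL),
            class = "midline_kinematics")
}

#' Midline curvature of the travelling wave
#'
#' @param kin A [midline_kinematics()].
#' @param s Midline coordinates in `[0, L]` (vectorised).
#' @param t Time.
#' @param amplitude_scale Multiplier on the undulation amplitude; used to ramp
#'   the motion down when a swimmer is frozen for coasting measurements.
#' @param extra Additional uniform curvature (steering command), added to the
#'   wave.
#' @return Curvature values (1/length).
#' @export
curvature <- function(kin, s, t, amplitude_scale = 1, extra = 0) {
  stopifnot(inherits(kin, "midline_kinematics"))
  if (any(s < 0 | s > kin$L)) abort("midline coordinate s outside [0, L]")
  A <- kin$A0 + (kin$AL - kin$A0) * s / kin$L
  amplitude_scale * A * sin(2 * pi * t / kin$Tp - 2 * pi * s / kin$L) + extra
}

#' Integrate a curvature profile into a planar midline curve
#'
#' Reconstructs the planar midline `r(s)` from a sampled curvature profile by
#' integrating the planar Frenet-Serret relations (tangent angle
#' `theta'(s) = k(s)`) with a fixed-step midpoint rule, then rigidly positions
#' the curve so that its (uniform-density) centre of mass and mean tangent
#' orientation take prescribed values. The discrete curve has total polyline
#' arclength exactly `max(s) - min(s)` and reproduces the input curvature to
#' second order in the grid spacing.
#'
#' @param s Monotone increasing arclength grid covering `[0, L]`.
#' @param k Curvature sampled at `s`.
#' @param com Target centre of mass, length-2 numeric.
#' @param angle Target mean tangent angle (radians).
#' @return A tibble of class `midline_curve` with columns `s`, `x`, `y`,
#'   `tx`, `ty` (unit tangents) and attribute `L` (arclength).
#' @examples
#' s <- seq(0, 0.1, length.out = 501)
#' straight <- integrate_midline(s, rep(0, length(s)))
#' @export
integrate_midline <- function(s, k, com = c(0, 0), angle = 0) {
  if (length(s) < 2 || is.unsorted(s, strictly = TRUE)) {
    abort("s must be a strictly increasing grid")
  }
  stopifnot(length(k) == length(s), length(com) == 2)
  n <- length(s)
  h <- diff(s)
  kmid <- (k[-1] + k[-n]) / 2
  theta <- c(0, cumsum(kmid * h))
  # midpoint tangent angle for the position update (second order)
  theta_half <- theta[-n] + kmid * h / 2
  x <- c(0, cumsum(h * cos(theta_half)))
  y <- c(0, cumsum(h * sin(theta_half)))
  # arclength-weighted means (trapezoid weights)
  wts <- c(h / 2, 0) + c(0, h / 2)
  wts <- wts / sum(wts)
  theta_bar <- sum(wts * theta)
  rot <- angle - theta_bar
  cr <- cos(rot); sr <- sin(rot)
  xr <- cr * x - sr * y
  yr <- sr * x + cr * y
  xr <- xr - sum(wts * xr) + com[1]
  yr <- yr - sum(wts * yr) + com[2]
  th <- theta + rot
  out <- tibble(s = s, x = xr, y = yr, tx = cos(th), ty = sin(th))
  class(out) <- c("midline_curve", class(out))
  attr(out, "L") <- s[n] - s[1]
  out
}

#' Midline curve of a swimmer at a given time
#'
#' Convenience wrapper: samples the travelling-wave curvature of `kin` on a
#' uniform grid (1000 points by default) and integrates it with
#' [integrate_midline()].
#'
#' @inheritParams curvature
#' @param n Number of arclength samples.
#' @param com,angle Rigid positioning, see [integrate_midline()].
#' @return A `midline_curve` tibble.
#' @export
midline_at <- function(kin, t, n = 1000, com = c(0, 0), angle = 0,
                       amplitude_scale = 1, extra = 0) {
  s <- seq(0, kin$L, length.out = n)
  integrate_midline(s, curvature(kin, s, t, amplitude_scale, extra),
                    com = com, angle = angle)
}

#' Paired surface points of a sensor location
#'
#' Each sensor is indexed by a single midline coordinate `s` and expands to two
#' surface locations offset by the local half-width `w(s)` along the midline
#' normal: `x1` on the upper side (left of the tangent) and `x2` on the lower
#' side.
#'
#' @param shape A [swimmer_shape()].
#' @param midline A `midline_curve` from [integrate_midline()].
#' @param s Midline coordinates (vectorised).
#' @return A tibble with columns `s`, `x_upper`, `y_upper`, `x_lower`,
#'   `y_lower`.
#' @export
surface_points <- function(shape, midline, s) {
  stopifnot(inherits(midline, "midline_curve"))
  w <- half_width(shape, s)
  fx <- splinefun(midline$s, midline$x)
  fy <- splinefun(midline$s, midline$y)
  ftx <- splinefun(midline$s, midline$tx)
  fty <- splinefun(midline$s, midline$ty)
  tx <- ftx(s); ty <- fty(s)
  nrm <- sqrt(tx^2 + ty^2)
  tx <- tx / nrm; ty <- ty / nrm
  # upper = left of the tangent direction
  nx <- -ty; ny <- tx
  tibble(
    s = s,
    x_upper = fx(s) + w * nx, y_upper = fy(s) + w * ny,
    x_lower = fx(s) - w * nx, y_lower = fy(s) - w * ny
  )
}

#' Closed surface polygon of a swimmer body
#'
#' Builds the closed body outline (upper side head to tail, then lower side
#' tail to head; first vertex repeated last) used by
#' [characteristic_function()].
#'
#' @inheritParams surface_points
#' @param n Number of midline stations per side.
#' @return A two-column matrix of vertices; first and last rows coincide.
#' @export
surface_polygon <- function(shape, midline, n = 200) {
  s <- seq(0, shape$L, length.out = n)
  sp <- surface_points(shape, midline, s)
  xs <- c(sp$x_upper, rev(sp$x_lower))
  ys <- c(sp$y_upper, rev(sp$y_lower))
  cbind(c(xs, xs[1]), c(ys, ys[1]))
}
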