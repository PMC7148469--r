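#' Uniform Cartesian grid for the 2D flow solver
#'
#' Cell-centred uniform grid. Two boundary treatments are supported:
#' `"periodic"` in both directions, and `"channel"` (periodic in x, free-slip
#' rigid walls at the two y boundaries), a towing-tank-like setting for
#' schooling runs. The spacing must be isotropic (`Lx/nx == Ly/ny`).
#'
#' @param nx,ny Cell counts.
#' @param Lx,Ly Domain extents.
#' @param bc `"periodic"` or `"channel"`.
#' @return An object of class `flow_grid`.
#' @export
flow_grid <- function(nx, ny, Lx = 1, Ly = Lx * ny / nx,
                      bc = c("periodic", "channel")) {
  bc <- match.arg(bc)
  stopifnot(nx >= 4, ny >= 4, Lx > 0, Ly > 0)
  hx <- Lx / nx
  hy <- Ly / ny
  if (abs(hx - hy) > 1e-12 * hx) abort("grid spacing must be isotropic")
  structure(list(nx = nx, ny = ny, h = hx, Lx = Lx, Ly = Ly, bc = bc,
                 x = (seq_len(nx) - 0.5) * hx, y = (seq_len(ny) - 0.5) * hy),
            class = "flow_grid")
}

#' Velocity-pressure flow state
#'
#' @param grid A [flow_grid()].
#' @param u,v Velocity component matrices (`nx` by `ny`), recycled from
#'   scalars.
#' @param t Current time.
#' @return An object of class `flow_state`.
#' @export
flow_state <- function(grid, u = 0, v = 0, t = 0) {
  mk <- function(a) {
    if (is.matrix(a)) {
      stopifnot(nrow(a) == grid$nx, ncol(a) == grid$ny)
      a
    } else {
      matrix(a, grid$nx, grid$ny)
    }
  }
  structure(list(grid = grid, u = mk(u), v = mk(v),
                 p = matrix(0, grid$nx, grid$ny), t = t),
            class = "flow_state")
}

#' Solver configuration
#'
#' @param nu Kinematic viscosity.
#' @param dt Time step; checked against advective and diffusive stability
#'   bounds at every step.
#' @param cfl Advective CFL limit (fraction of `h / max|u|`).
#' @param beta Upwind blending coefficient of the flux-form advection scheme
#'   (0 = purely centred, second order; small positive values add a
#'   conservative Rusanov-type dissipation).
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(nu, dt, cfl = 0.4, beta = 0.1) {
  stopifnot(nu > 0, dt > 0, cfl > 0, cfl <= 1, beta >= 0, beta <= 1)
  structure(list(nu = nu, dt = dt, cfl = cfl, beta = beta),
            class = "solver_config")
}

# ---- shifted-index helpers -------------------------------------------------
# parity: +1 even reflection at y walls (u, p), -1 odd reflection (v).
shift_xp <- function(A) A[c(2:nrow(A), 1), , drop = FALSE]
shift_xm <- function(A) A[c(nrow(A), 1:(nrow(A) - 1)), , drop = FALSE]

shift_yp <- function(A, bc, parity = 1) {
  m <- ncol(A)
  if (bc == "periodic") {
    A[, c(2:m, 1), drop = FALSE]
  } else {
    cbind(A[, 2:m, drop = FALSE], parity * A[, m])
  }
}
shift_ym <- function(A, bc, parity = 1) {
  m <- ncol(A)
  if (bc == "periodic") {
    A[, c(m, 1:(m - 1)), drop = FALSE]
  } else {
    cbind(parity * A[, 1], A[, 1:(m - 1), drop = FALSE])
  }
}

laplacian <- function(A, h, bc, parity = 1) {
  (shift_xp(A) + shift_xm(A) + shift_yp(A, bc, parity) +
     shift_ym(A, bc, parity) - 4 * A) / h^2
}

# Central divergence of (u, v); v is odd across channel walls.
div_central <- function(u, v, h, bc) {
  (shift_xp(u) - shift_xm(u)) / (2 * h) +
    (shift_yp(v, bc, -1) - shift_ym(v, bc, -1)) / (2 * h)
}

grad_x <- function(p, h) (shift_xp(p) - shift_xm(p)) / (2 * h)
grad_y <- function(p, h, bc) (shift_yp(p, bc, 1) - shift_ym(p, bc, 1)) / (2 * h)

# Conservative flux-form advection of scalar q by (u, v).
# F_{i+1/2} = ubar * qbar - beta * |ubar| * (q_{i+1} - q_i) / 2, then the
# flux difference; telescoping guarantees momentum conservation to round-off
# in periodic domains for any beta.
advect <- function(q, u, v, h, bc, beta, parity_q) {
  qxp <- shift_xp(q)
  uf <- (u + shift_xp(u)) / 2
  Fx <- uf * (q + qxp) / 2 - beta * abs(uf) * (qxp - q) / 2
  qyp <- shift_yp(q, bc, parity_q)
  vf <- (v + shift_yp(v, bc, -1)) / 2
  if (bc == "channel") vf[, ncol(vf)] <- 0   # no flux through the wall
  Fy <- vf * (q + qyp) / 2 - beta * abs(vf) * (qyp - q) / 2
  Fym <- shift_ym(Fy, bc = "periodic")       # face below cell j is face of j-1
  if (bc == "channel") Fym[, 1] <- 0
  (Fx - shift_xm(Fx)) / h + (Fy - Fym) / h
}

# ---- Poisson solver --------------------------------------------------------
# Inverts the composite central-difference div(grad(.)) operator with FFTs.
# Periodic: direct; channel: even extension in y (Neumann walls). Null modes
# (mean and Nyquist, where the wide-stencil symbol vanishes) are projected
# out.
poisson_dg <- function(rhs, h, bc) {
  if (bc == "channel") {
    rhs <- cbind(rhs, rhs[, rev(seq_len(ncol(rhs))), drop = FALSE])
  }
  nx <- nrow(rhs); ny <- ncol(rhs)
  kx <- (seq_len(nx) - 1) / nx
  ky <- (seq_len(ny) - 1) / ny
  sym <- -(outer(sin(2 * pi * kx)^2, rep(1, ny)) +
             outer(rep(1, nx), sin(2 * pi * ky)^2)) / h^2
  ph <- fft(rhs)
  null_modes <- abs(sym) < 1e-14 * max(abs(sym))
  sym[null_modes] <- 1
  ph <- ph / sym
  ph[null_modes] <- 0
  p <- Re(fft(ph, inverse = TRUE)) / (nx * ny)
  if (bc == "channel") p <- p[, seq_len(ncol(p) / 2), drop = FALSE]
  p
}

# The composite central-difference div(grad(.)) operator decouples the grid
# into four parity sublattices; its range is the set of fields with zero mean
# on each sublattice. Absorb each sublattice's compatibility excess inside
# the bodies (chi-weighted) -- or uniformly when there are none -- so the
# Poisson problem is solvable exactly and the projected field is
# divergence-free to round-off wherever chi = 0.
balance_rhs <- function(rhs, chi, bc = "periodic") {
  nx <- nrow(rhs); ny <- ncol(rhs)
  pxm <- outer(seq_len(nx) %% 2, rep(1, ny))
  pym <- outer(rep(1, nx), seq_len(ny) %% 2)
  classes <- if (bc == "periodic") {
    # four parity sublattices
    list(pxm == 0 & pym == 0, pxm == 0 & pym == 1,
         pxm == 1 & pym == 0, pxm == 1 & pym == 1)
  } else {
    # y walls (even extension): only the per-x-parity means are null modes
    list(pxm == 0, pxm == 1)
  }
  for (cls in classes) {
    excess <- sum(rhs[cls])
    if (excess == 0) next
    if (!is.null(chi) && sum(chi[cls]) > 0) {
      rhs[cls] <- rhs[cls] - excess * chi[cls] / sum(chi[cls])
    } else {
      rhs[cls] <- rhs[cls] - excess / sum(cls)
    }
  }
  rhs
}

#' Brinkman characteristic function of a body
#'
#' Mollified Heaviside of the signed distance to a closed surface polygon:
#' 1 deep inside the body, 0 far outside, with a linear transition of
#' half-width `eps` (default `2h`) across the surface, which makes the
#' discrete body area second-order accurate.
#'
#' @param poly Two-column vertex matrix of a closed, non-self-intersecting
#'   curve; the first and last vertices must coincide.
#' @param grid A [flow_grid()].
#' @param eps Transition half-width; default `2 * grid$h`.
#' @return A list with the field `chi` (`nx` by `ny` matrix in `[0, 1]`) and
#'   the index set `band` of cells with `0 < chi` (used to localise body
#'   velocity evaluation).
#' @export
characteristic_function <- function(poly, grid, eps = 2 * grid$h) {
  stopifnot(is.matrix(poly), ncol(poly) == 2, nrow(poly) >= 4)
  if (max(abs(poly[1, ] - poly[nrow(poly), ])) > 1e-12) {
    abort("open curve: first and last polygon vertices must coincide")
  }
  # bodies crossing a periodic boundary act through their shifted images
  xshifts <- 0
  yshifts <- 0
  margin <- 3 * eps
  if (min(poly[, 1]) < margin) xshifts <- c(xshifts, grid$Lx)
  if (max(poly[, 1]) > grid$Lx - margin) xshifts <- c(xshifts, -grid$Lx)
  if (grid$bc == "periodic") {
    if (min(poly[, 2]) < margin) yshifts <- c(yshifts, grid$Ly)
    if (max(poly[, 2]) > grid$Ly - margin) yshifts <- c(yshifts, -grid$Ly)
  }
  if (length(xshifts) > 1 || length(yshifts) > 1) {
    chi <- matrix(0, grid$nx, grid$ny)
    for (sx in xshifts) {
      for (sy in yshifts) {
        img <- chi_single(cbind(poly[, 1] + sx, poly[, 2] + sy), grid, eps)
        chi <- pmax(chi, img)
      }
    }
    return(list(chi = chi, band = which(chi > 0, arr.ind = TRUE)))
  }
  chi_wrap <- chi_single(poly, grid, eps)
  list(chi = chi_wrap, band = which(chi_wrap > 0, arr.ind = TRUE))
}

chi_single <- function(poly, grid, eps) {
  nx <- grid$nx; ny <- grid$ny
  chi <- matrix(0, nx, ny)
  # restrict work to the bounding box plus margin
  margin <- 3 * eps
  ix <- which(grid$x >= min(poly[, 1]) - margin & grid$x <= max(poly[, 1]) + margin)
  iy <- which(grid$y >= min(poly[, 2]) - margin & grid$y <= max(poly[, 2]) + margin)
  if (length(ix) == 0 || length(iy) == 0) return(chi)
  px <- rep(grid$x[ix], times = length(iy))
  py <- rep(grid$y[iy], each = length(ix))
  d2 <- rep(Inf, length(px))
  crossings <- integer(length(px))
  nseg <- nrow(poly) - 1
  for (k in seq_len(nseg)) {
    ax <- poly[k, 1]; ay <- poly[k, 2]
    bx <- poly[k + 1, 1]; by <- poly[k + 1, 2]
    ex <- bx - ax; ey <- by - ay
    len2 <- ex^2 + ey^2
    if (len2 < 1e-30) next
    tt <- pmin(pmax(((px - ax) * ex + (py - ay) * ey) / len2, 0), 1)
    dx <- px - (ax + tt * ex); dy <- py - (ay + tt * ey)
    d2 <- pmin(d2, dx^2 + dy^2)
    cr <- ((ay > py) != (by > py)) &
      (px < ax + (py - ay) * ex / (ey + (ey == 0)))
    crossings <- crossings + cr
  }
  inside <- crossings %% 2L == 1L
  sd <- sqrt(d2) * ifelse(inside, -1, 1)
  vals <- pmin(pmax((eps - sd) / (2 * eps), 0), 1)
  chi[ix, iy] <- matrix(vals, nrow = length(ix), ncol = length(iy))
  chi
}

#' Explicit velocity update (pre-projection)
#'
#' Advances the velocity by one explicit Euler step containing advection,
#' diffusion and the Brinkman penalization term `chi * (us - u)` (penalty
#' coefficient `lambda = 1/dt`). The returned state is not yet
#' divergence-free; follow with [pressure_projection()].
#'
#' @param state A [flow_state()].
#' @param pen Penalization field: a list with matrices `chi` (total body
#'   indicator in `[0, 1]`), `usx`, `usy` (imposed body velocity). `NULL`
#'   for body-free flow.
#' @param cfg A [solver_config()].
#' @return Updated `flow_state` (pre-projection).
#' @export
advance_velocity <- function(state, pen, cfg) {
  g <- state$grid; h <- g$h; dt <- cfg$dt
  umax <- max(abs(state$u), abs(state$v), 1e-12)
  dt_adv <- cfg$cfl * h / umax
  dt_dif <- h^2 / (4 * cfg$nu)
  if (dt > dt_adv + 1e-15) {
    abort(sprintf("CFL violation: dt = %.3g exceeds advective bound %.3g",
                  dt, dt_adv))
  }
  if (dt > dt_dif + 1e-15) {
    abort(sprintf("CFL violation: dt = %.3g exceeds diffusive bound %.3g",
                  dt, dt_dif))
  }
  u <- state$u; v <- state$v; bc <- g$bc
  un <- u + dt * (-advect(u, u, v, h, bc, cfg$beta, parity_q = 1) +
                    cfg$nu * laplacian(u, h, bc, parity = 1))
  vn <- v + dt * (-advect(v, u, v, h, bc, cfg$beta, parity_q = -1) +
                    cfg$nu * laplacian(v, h, bc, parity = -1))
  if (!is.null(pen)) {
    un <- un + pen$chi * (pen$usx - u)
    vn <- vn + pen$chi * (pen$usy - v)
  }
  state$u <- un; state$v <- vn
  state$t <- state$t + dt
  state
}

#' Pressure projection step
#'
#' Solves the pressure Poisson problem for the pre-projection velocity and
#' corrects it by `-dt * grad(p)`. Inside bodies the divergence source is
#' switched off (the body-deformation correction: the right-hand side is
#' `(1 - chi) * div(u) / dt`), so the projected field is divergence-free to
#' round-off wherever `chi = 0` while body deformation is not fought by the
#' pressure. The compatibility mass needed by the periodic Poisson problem is
#' absorbed inside the bodies.
#'
#' @inheritParams advance_velocity
#' @return `flow_state` with corrected velocities and the pressure field `p`.
#' @export
pressure_projection <- function(state, pen = NULL, cfg) {
  g <- state$grid; h <- g$h; dt <- cfg$dt
  dv <- div_central(state$u, state$v, h, g$bc)
  if (is.null(pen)) {
    rhs <- balance_rhs(dv / dt, NULL, g$bc)
  } else {
    rhs <- balance_rhs((1 - pen$chi) * dv / dt, pen$chi, g$bc)
  }
  p <- poisson_dg(rhs, h, g$bc)
  state$u <- state$u - dt * grad_x(p, h)
  state$v <- state$v - dt * grad_y(p, h, g$bc)
  state$p <- p
  state
}

#' One full solver step (advance + project)
#'
#' @inheritParams advance_velocity
#' @return Updated, projected `flow_state`.
#' @export
step_flow <- function(state, pen = NULL, cfg) {
  pressure_projection(advance_velocity(state, pen, cfg), pen, cfg)
}

#' Central-difference divergence of a flow state
#'
#' @param state A [flow_state()].
#' @return Matrix of cell-centred divergence values.
#' @export
flow_divergence <- function(state) {
  div_central(state$u, state$v, state$grid$h, state$grid$bc)
}

#' Total kinetic energy of a flow state
#'
#' @param state A [flow_state()].
#' @return `sum((u^2 + v^2) / 2) * h^2`.
#' @export
kinetic_energy <- function(state) {
  sum(state$u^2 + state$v^2) / 2 * state$grid$h^2
}

#' Taylor-Green vortex initial condition
#'
#' The classical decaying-vortex benchmark `u = sin(x) cos(y)`,
#' `v = -cos(x) sin(y)` on a periodic `[0, 2*pi]^2` box; its kinetic energy
#' decays analytically as `exp(-4 * nu * t)` (wavenumber 1).
#'
#' @param grid A periodic [flow_grid()] with `Lx = Ly = 2*pi`.
#' @return A `flow_state`.
#' @export
taylor_green <- function(grid) {
  stopifnot(grid$bc == "periodic", abs(grid$Lx - 2 * pi) < 1e-9)
  u <- outer(sin(grid$x), cos(grid$y))
  v <- -outer(cos(grid$x), sin(grid$y))
  flow_state(grid, u, v)
}

# Bilinear interpolation of a cell-centred field at arbitrary points.
interp_bilinear <- function(A, grid, px, py) {
  h <- grid$h; nx <- grid$nx; ny <- grid$ny
  gx <- px / h - 0.5
  gy <- py / h - 0.5
  i0 <- floor(gx); j0 <- floor(gy)
  fx <- gx - i0; fy <- gy - j0
  wrap <- function(i, n) ((i %% n) + n) %% n + 1
  clampi <- function(i, n) pmin(pmax(i, 0), n - 1) + 1
  if (grid$bc == "periodic") {
    i1 <- wrap(i0, nx); i2 <- wrap(i0 + 1, nx)
    j1 <- wrap(j0, ny); j2 <- wrap(j0 + 1, ny)
  } else {
    i1 <- wrap(i0, nx); i2 <- wrap(i0 + 1, nx)
    j1 <- clampi(j0, ny); j2 <- clampi(j0 + 1, ny)
  }
  A[cbind(i1, j1)] * (1 - fx) * (1 - fy) +
    A[cbind(i2, j1)] * fx * (1 - fy) +
    A[cbind(i1, j2)] * (1 - fx) * fy +
    A[cbind(i2, j2)] * fx * fy
}
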