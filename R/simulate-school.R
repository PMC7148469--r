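#' Simulate a school of self-propelled swimmers (reduced fidelity)
#'
#' Desk-scale demonstrator coupling the penalized Navier-Stokes solver with
#' undulating swimmer bodies and the closed-loop schooling controllers. Each
#' swimmer deforms according to its travelling-wave curvature, feeds its body
#' velocity into the flow through the Brinkman term, and recovers its rigid
#' translation/rotation by projecting the penalized flow momentum onto rigid
#' body modes. A follower can be frozen (curvature ramped linearly to zero
#' over `protocol$ramp` time units after `protocol$freeze_time`) so that the
#' surface signals recorded at `protocol$record_time` reflect the environment
#' rather than its own motion.
#'
#' This solver runs at far coarser resolution than production simulations of
#' schooling hydrodynamics; it validates the numerical building blocks and
#' produces qualitatively sensible flow fields, not converged physics.
#'
#' @param swimmers List of swimmer descriptions; each element is a list with
#'   `shape` ([swimmer_shape()]), `kin` ([midline_kinematics()]), `com`
#'   (length-2 initial centre of mass), `angle` (initial orientation) and
#'   `role` (`"leader"` or `"follower"`).
#' @param grid A [flow_grid()].
#' @param cfg A [solver_config()].
#' @param t_end Final time.
#' @param protocol List with `freeze_time` (start of the follower coast,
#'   `Inf` to disable), `ramp` (duration of the amplitude ramp-down, default
#'   one period) and `record_time` (surface signals recorded at the step
#'   closest to this time; default `t_end`).
#' @param control List with `enabled` (logical) and `gain` (steering gain,
#'   1/length units are applied internally through the body length).
#' @param n_midline Arclength samples for body integration.
#' @param n_poly Midline stations per side for the surface polygon.
#' @param s_max_frac Tail-exclusion cutoff as a fraction of `L`: recorded
#'   signals stop at `s_max = s_max_frac * L`.
#' @param n_record Number of midline stations in the recorded signal grid.
#' @param ramp_up Smooth-start duration: the undulation amplitude grows
#'   linearly from rest over this many time units, avoiding the violent
#'   recoil of an impulsive full-amplitude start.
#' @param verbose Print progress every 20 steps.
#' @return A list of class `school_simulation` with elements `trajectories`
#'   (tibble: `t`, `id`, `role`, `x`, `y`, `theta`, `Tp`, `kC`), `signals`
#'   (tibble: `s`, `side`, `pressure`, `pressure_gradient`, `shear`, recorded
#'   for the follower), `follower_midline` (the follower's world-frame
#'   midline at the record step), `state` (final [flow_state()]), `chi`
#'   (final total body indicator) and `params`.
#' @export
simulate_school <- function(swimmers, grid, cfg, t_end,
                            protocol = list(freeze_time = Inf, ramp = 1,
                                            record_time = NULL),
                            control = list(enabled = TRUE, gain = 1),
                            ramp_up = 1, n_midline = 300, n_poly = 160,
                            s_max_frac = 0.95, n_record = 64,
                            verbose = FALSE) {
  ns <- length(swimmers)
  stopifnot(ns >= 1)
  protocol$ramp <- protocol$ramp %||% 1
  record_time <- protocol$record_time %||% t_end
  freeze_time <- protocol$freeze_time %||% Inf
  dt <- cfg$dt
  nsteps <- max(1L, round(t_end / dt))
  record_step <- max(1L, min(nsteps, round(record_time / dt)))

  follower_id <- which(vapply(swimmers, function(s) identical(s$role, "follower"),
                              logical(1)))
  follower_id <- if (length(follower_id)) follower_id[1] else 1L

  # per-swimmer dynamic state
  sw <- lapply(swimmers, function(s) {
    list(shape = s$shape, kin = s$kin,
         X = as.numeric(s$com), Xu = as.numeric(s$com),
         theta = s$angle %||% 0,
         U = c(0, 0), Omega = 0, tau = 0, Tp = s$kin$Tp, kC = 0,
         y0 = s$com[2], x0 = s$com[1],
         ctrl = controller_state(), role = s$role %||% "leader",
         prev_bm = NULL)
  })

  # domain fit check (channel walls only; periodic wraps)
  if (grid$bc == "channel") {
    for (s in sw) {
      if (s$X[2] - s$shape$L < 0 || s$X[2] + s$shape$L > grid$Ly) {
        abort("swimmer body too close to the domain wall")
      }
    }
  }

  state <- flow_state(grid)
  s_grid <- seq(0, sw[[1]]$shape$L, length.out = n_midline)
  sub <- unique(round(seq(1, n_midline, length.out = 50)))
  school_drift <- 0
  traj <- vector("list", nsteps)
  signals <- NULL
  follower_midline <- NULL
  chi_tot <- NULL

  rot2 <- function(th) matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)

  for (step in seq_len(nsteps)) {
    t_now <- (step - 1) * dt
    chi_tot <- matrix(0, grid$nx, grid$ny)
    usx_acc <- matrix(0, grid$nx, grid$ny)
    usy_acc <- matrix(0, grid$nx, grid$ny)
    chi_list <- vector("list", ns)
    world_midlines <- vector("list", ns)

    for (i in seq_len(ns)) {
      s_i <- sw[[i]]
      frozen <- i == follower_id && t_now >= freeze_time
      scale <- if (ramp_up > 0) min(1, t_now / ramp_up) else 1
      if (frozen) {
        scale <- scale * max(0, 1 - (t_now - freeze_time) / protocol$ramp)
      }
      # phase advanced with the controlled period: evaluate the wave at tau
      A <- s_i$kin$A0 + (s_i$kin$AL - s_i$kin$A0) * s_grid / s_i$kin$L
      kvec <- scale * A * sin(2 * pi * s_i$tau - 2 * pi * s_grid / s_i$kin$L) +
        (if (frozen) 0 else s_i$kC)
      bm <- integrate_midline(s_grid, kvec)
      # register the deformation so it carries no angular momentum in the
      # body frame: accumulate a counter-rotation cancelling the apparent
      # rotation rate of the deforming midline (linear momentum is already
      # zero because the centre of mass is pinned)
      if (!is.null(s_i$prev_bm)) {
        wts <- rep(1 / n_midline, n_midline)
        dxd <- bm$x - s_i$prev_bm$x
        dyd <- bm$y - s_i$prev_bm$y
        omega_def <- sum(wts * (s_i$prev_bm$x * dyd - s_i$prev_bm$y * dxd)) /
          sum(wts * (s_i$prev_bm$x^2 + s_i$prev_bm$y^2))
        sw[[i]]$phi <- (s_i$phi %||% 0) - omega_def
      }
      phi <- sw[[i]]$phi %||% 0
      sw[[i]]$prev_bm <- bm
      if (phi != 0) {
        cp <- cos(phi); sp <- sin(phi)
        bm_rot <- bm
        bm_rot$x <- cp * bm$x - sp * bm$y
        bm_rot$y <- sp * bm$x + cp * bm$y
        bm_rot$tx <- cp * bm$tx - sp * bm$ty
        bm_rot$ty <- sp * bm$tx + cp * bm$ty
        bm <- bm_rot
      }
      # deformation velocity in the (registered) body frame
      if (is.null(s_i$prev_bm_reg)) {
        defx <- numeric(n_midline); defy <- numeric(n_midline)
      } else {
        defx <- (bm$x - s_i$prev_bm_reg$x) / dt
        defy <- (bm$y - s_i$prev_bm_reg$y) / dt
      }
      sw[[i]]$prev_bm_reg <- bm
      R <- rot2(s_i$theta)
      wx <- R[1, 1] * bm$x + R[1, 2] * bm$y + s_i$X[1]
      wy <- R[2, 1] * bm$x + R[2, 2] * bm$y + s_i$X[2]
      wtx <- R[1, 1] * bm$tx + R[1, 2] * bm$ty
      wty <- R[2, 1] * bm$tx + R[2, 2] * bm$ty
      wm <- tibble(s = s_grid, x = wx, y = wy, tx = wtx, ty = wty)
      class(wm) <- c("midline_curve", class(wm))
      world_midlines[[i]] <- wm
      poly <- surface_polygon(s_i$shape, wm, n = n_poly)
      cf <- characteristic_function(poly, grid)
      chi_list[[i]] <- cf
      if (nrow(cf$band) > 0) {
        bx <- grid$x[cf$band[, 1]]
        by <- grid$y[cf$band[, 2]]
        # nearest midline station (subsampled) for the deformation velocity;
        # minimal-image differences handle bodies straddling a periodic edge
        ddx <- min_image(outer(bx, wx[sub], "-"), grid$Lx)
        ddy <- outer(by, wy[sub], "-")
        if (grid$bc == "periodic") ddy <- min_image(ddy, grid$Ly)
        dmat <- ddx^2 + ddy^2
        nearest <- sub[max.col(-dmat, ties.method = "first")]
        defw_x <- R[1, 1] * defx + R[1, 2] * defy
        defw_y <- R[2, 1] * defx + R[2, 2] * defy
        rx <- min_image(bx - s_i$X[1], grid$Lx)
        ry <- by - s_i$X[2]
        if (grid$bc == "periodic") ry <- min_image(ry, grid$Ly)
        us_bx <- s_i$U[1] - s_i$Omega * ry + defw_x[nearest]
        us_by <- s_i$U[2] + s_i$Omega * rx + defw_y[nearest]
        cvals <- cf$chi[cf$band]
        usx_acc[cf$band] <- usx_acc[cf$band] + cvals * us_bx
        usy_acc[cf$band] <- usy_acc[cf$band] + cvals * us_by
        chi_tot[cf$band] <- chi_tot[cf$band] + cvals
      }
    }
    pos <- chi_tot > 0
    usx <- matrix(0, grid$nx, grid$ny); usy <- usx
    usx[pos] <- usx_acc[pos] / chi_tot[pos]
    usy[pos] <- usy_acc[pos] / chi_tot[pos]
    pen <- list(chi = pmin(chi_tot, 1), usx = usx, usy = usy)

    state <- step_flow(state, pen, cfg)

    # momentum transfer back to the bodies
    mean_ux <- 0
    for (i in seq_len(ns)) {
      cf <- chi_list[[i]]
      m <- sum(cf$chi)
      if (m <= 0) next
      Ux <- sum(cf$chi * state$u) / m
      Uy <- sum(cf$chi * state$v) / m
      bx <- grid$x[cf$band[, 1]]; by <- grid$y[cf$band[, 2]]
      rx <- min_image(bx - sw[[i]]$X[1], grid$Lx)
      ry <- by - sw[[i]]$X[2]
      if (grid$bc == "periodic") ry <- min_image(ry, grid$Ly)
      cvals <- cf$chi[cf$band]
      uloc <- state$u[cf$band]; vloc <- state$v[cf$band]
      inertia <- sum(cvals * (rx^2 + ry^2))
      Om <- if (inertia > 0) {
        sum(cvals * (rx * (vloc - Uy) - ry * (uloc - Ux))) / inertia
      } else 0
      sw[[i]]$U <- c(Ux, Uy)
      sw[[i]]$Omega <- Om
      sw[[i]]$X <- sw[[i]]$X + dt * c(Ux, Uy)
      sw[[i]]$Xu <- sw[[i]]$Xu + dt * c(Ux, Uy)
      sw[[i]]$X[1] <- sw[[i]]$X[1] %% grid$Lx
      if (grid$bc == "periodic") sw[[i]]$X[2] <- sw[[i]]$X[2] %% grid$Ly
      sw[[i]]$theta <- sw[[i]]$theta + dt * Om
      mean_ux <- mean_ux + Ux / ns
    }
    school_drift <- school_drift + dt * mean_ux

    # schooling controllers
    for (i in seq_len(ns)) {
      s_i <- sw[[i]]
      frozen <- i == follower_id && t_now >= freeze_time
      L <- s_i$shape$L
      if (isTRUE(control$enabled) && !frozen) {
        x_ref <- s_i$x0 + school_drift
        dx <- max(min((x_ref - s_i$Xu[1]) / L, 0.8), -0.8)
        dy <- (s_i$Xu[2] - s_i$y0) / L
        dtheta <- s_i$theta
        sw[[i]]$ctrl <- update_controller(s_i$ctrl, dx, dy, dtheta,
                                          weight = dt / s_i$kin$Tp)
        sw[[i]]$Tp <- period_control(s_i$kin$Tp, dx)
        sw[[i]]$kC <- steering_curvature(sw[[i]]$ctrl,
                                         gain = (control$gain %||% 1) / L)
      }
      sw[[i]]$tau <- s_i$tau + dt / sw[[i]]$Tp
    }

    traj[[step]] <- tibble(
      t = t_now + dt,
      id = seq_len(ns),
      role = vapply(sw, function(s) s$role, character(1)),
      x = vapply(sw, function(s) s$Xu[1], numeric(1)),
      y = vapply(sw, function(s) s$Xu[2], numeric(1)),
      theta = vapply(sw, function(s) s$theta, numeric(1)),
      Tp = vapply(sw, function(s) s$Tp, numeric(1)),
      kC = vapply(sw, function(s) s$kC, numeric(1))
    )

    if (step == record_step) {
      signals <- record_surface_signals(
        state, sw[[follower_id]], world_midlines[[follower_id]],
        cfg, s_max_frac, n_record)
      follower_midline <- world_midlines[[follower_id]]
    }
    if (verbose && step %% 20 == 0) {
      message(sprintf("t = %.3f / %.3f  max|u| = %.3f  E = %.3e",
                      t_now + dt, t_end, max(abs(state$u), abs(state$v)),
                      kinetic_energy(state)))
    }
  }

  structure(list(
    trajectories = dplyr::bind_rows(traj),
    signals = signals,
    follower_midline = follower_midline,
    state = state,
    chi = chi_tot,
    params = list(dt = dt, t_end = t_end, protocol = protocol,
                  control = control, follower = follower_id)
  ), class = "school_simulation")
}

# Sample pressure and near-wall tangential velocity on both sides of a body
# and reduce them to pressure-gradient and shear signals.
record_surface_signals <- function(state, swimmer, midline, cfg,
                                   s_max_frac, n_record) {
  grid <- state$grid
  shape <- swimmer$shape
  s_max <- s_max_frac * shape$L
  s_rec <- seq(0, s_max, length.out = n_record)
  sp <- surface_points(shape, midline, s_rec)
  ftx <- splinefun(midline$s, midline$tx)
  fty <- splinefun(midline$s, midline$ty)
  tx <- ftx(s_rec); ty <- fty(s_rec)
  nrm <- sqrt(tx^2 + ty^2); tx <- tx / nrm; ty <- ty / nrm
  nxv <- -ty; nyv <- tx
  h <- grid$h
  out <- purrr::map_dfr(c("upper", "lower"), function(side) {
    sgn <- if (side == "upper") 1 else -1
    px <- if (side == "upper") sp$x_upper else sp$x_lower
    py <- if (side == "upper") sp$y_upper else sp$y_lower
    pr <- interp_bilinear(state$p, grid, px, py)
    ut <- numeric(length(s_rec))
    uts <- lapply(c(1, 2), function(m) {
      qx <- px + sgn * m * h * nxv
      qy <- py + sgn * m * h * nyv
      uu <- interp_bilinear(state$u, grid, qx, qy) - swimmer$U[1]
      vv <- interp_bilinear(state$v, grid, qx, qy) - swimmer$U[2]
      uu * tx + vv * ty
    })
    shear <- shear_from_velocity(uts[[1]], uts[[2]], h, 2 * h, cfg$nu)
    pg <- smooth_pressure_gradient(s_rec, pr, s_out = s_rec)
    tibble(s = s_rec, side = side, pressure = pr,
           pressure_gradient = pg$value, shear = shear)
  })
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# shortest periodic displacement
min_image <- function(d, L) d - L * round(d / L)
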