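#' Tail-beat period control for station keeping
#'
#' A swimmer that lags behind its desired streamwise station beats faster, one
#' that overshoots beats slower. The controlled period is `Tp * (1 - dx)` with
#' `dx` the signed, dimensionless streamwise deviation. Under the default
#' convention (`lag_positive = TRUE`, the one used by [simulate_school()])
#' positive `dx` means the swimmer lags behind its station, so the period
#' shrinks and the beat frequency rises, closing the gap; the flag flips the
#' convention for callers that measure the deviation the other way round.
#'
#' @param Tp Nominal tail-beat period.
#' @param dx Streamwise deviation from the formation target, normalised by the
#'   body length.
#' @param lag_positive If `TRUE` (default) positive `dx` means the swimmer
#'   lags behind its station; set `FALSE` to flip the sign convention.
#' @return The controlled period `Tp * (1 - dx)`. Values `<= 0` (i.e.
#'   `|dx| >= 1`) are flagged with a `controller_saturation` warning.
#' @export
period_control <- function(Tp, dx, lag_positive = TRUE) {
  if (!lag_positive) dx <- -dx
  out <- Tp * (1 - dx)
  if (any(out <= 0)) {
    warn("period controller saturated: |dx| >= 1 gives a non-positive period",
         class = "controller_saturation")
  }
  out
}

#' Sign-gated product used by the steering controller
#'
#' Returns `|a| * b` when `a` and `b` have opposite signs (`a * b < 0`) and 0
#' otherwise. The steering law only acts when lateral displacement and heading
#' deflection disagree in sign, i.e. when the swimmer is not already turning
#' back towards its lane.
#'
#' @param a,b Numeric (vectorised).
#' @return `|a| * b` where `a * b < 0`, else 0.
#' @export
signed_gate <- function(a, b) {
  ifelse(a * b < 0, abs(a) * b, 0)
}

#' Steering curvature command
#'
#' Additional uniform midline curvature commanded to reduce the lateral
#' deviation `dy` and angular deflection `dtheta` of a swimmer relative to its
#' schooling lane. The command is the sum of three sign-gated terms combining
#' instantaneous values and their exponential moving averages (a PI-like law):
#' `[dy, <dtheta>] + [<dy>, dtheta] + [<dy>, <dtheta>]` with
#' `[a, b] = signed_gate(a, b)`.
#'
#' @param state A list (see [controller_state()]) with elements `dy`,
#'   `dtheta`, `dy_avg`, `dtheta_avg`.
#' @param gain Output gain converting the dimensionless gated sum into a
#'   curvature (1/length); default 1.
#' @return Steering curvature command.
#' @export
steering_curvature <- function(state, gain = 1) {
  gain * (signed_gate(state$dy, state$dtheta_avg) +
            signed_gate(state$dy_avg, state$dtheta) +
            signed_gate(state$dy_avg, state$dtheta_avg))
}

#' Controller state of one swimmer
#'
#' Tracks the deviations of a swimmer from its formation station: streamwise
#' `dx` and lateral `dy` offsets (normalised by body length), angular
#' deflection `dtheta` (radians), and exponential moving averages of `dy` and
#' `dtheta` with weight `dt/Tp`. Averages are initialised from the first
#' sample to avoid start-up bias.
#'
#' @param dx,dy,dtheta Initial deviations.
#' @return A list of class `controller_state`.
#' @export
controller_state <- function(dx = 0, dy = 0, dtheta = 0) {
  structure(list(dx = dx, dy = dy, dtheta = dtheta,
                 dy_avg = dy, dtheta_avg = dtheta, initialised = FALSE),
            class = "controller_state")
}

#' Exponential moving average update
#'
#' `new_avg = (1 - weight) * avg + weight * sample`. The running averages in
#' the steering controller use weight `dt/Tp`, approximating the integral term
#' of a PI controller.
#'
#' @param avg Previous average.
#' @param sample New sample.
#' @param weight Averaging weight in `(0, 1]`.
#' @return Updated average.
#' @export
ema_update <- function(avg, sample, weight) {
  if (any(weight <= 0 | weight > 1)) abort("ema weight must be in (0, 1]")
  (1 - weight) * avg + weight * sample
}

# Advance a controller_state with fresh deviation measurements.
update_controller <- function(state, dx, dy, dtheta, weight) {
  state$dx <- dx
  state$dy <- dy
  state$dtheta <- dtheta
  if (!state$initialised) {
    state$dy_avg <- dy
    state$dtheta_avg <- dtheta
    state$initialised <- TRUE
  } else {
    state$dy_avg <- ema_update(state$dy_avg, dy, weight)
    state$dtheta_avg <- ema_update(state$dtheta_avg, dtheta, weight)
  }
  state
}
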