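#' Piecewise-constant motor torque schedule
#'
#' Contiguous, non-overlapping intervals `[t_start, t_end)` with a constant
#' applied torque `tau` each.  Positive `tau` drives counterclockwise (CCW)
#' flagellar rotation, negative `tau` clockwise (CW); a pause is an interval
#' with `tau = 0`.
#'
#' @param t_start,t_end interval bounds (s)
#' @param tau applied torque per interval (g um^2/s^2)
#' @param label optional mode labels
#' @return object of class `motor_schedule`
#' @export
motor_schedule <- function(t_start, t_end, tau, label = NULL) {
  stopifnot(length(t_start) == length(t_end), length(tau) == length(t_start))
  o <- order(t_start)
  t_start <- t_start[o]; t_end <- t_end[o]; tau <- tau[o]
  if (any(t_end <= t_start)) stop("each segment needs t_start < t_end")
  if (length(t_start) > 1 &&
      any(abs(t_start[-1] - t_end[-length(t_end)]) > 1e-12)) {
    stop("schedule segments must be contiguous")
  }
  structure(list(t_start = t_start, t_end = t_end, tau = tau,
                 label = label %||% rep(NA_character_, length(tau)),
                 duration = t_end[length(t_end)] - t_start[1]),
            class = "motor_schedule")
}

#' @rdname motor_schedule
#' @param duration run length (s)
#' @export
schedule_constant <- function(tau, duration) {
  motor_schedule(0, duration, tau, label = if (tau > 0) "push" else
                 if (tau < 0) "cw" else "pause")
}

#' @rdname motor_schedule
#' @param durations named numeric vector of successive interval lengths (s)
#' @param taus torques for the same intervals
#' @export
schedule_sequence <- function(durations, taus) {
  stopifnot(length(durations) == length(taus))
  ends <- cumsum(durations)
  motor_schedule(c(0, ends[-length(ends)]), ends, taus, label = names(durations))
}

#' Wrapping-pause-push schedule for reorientation experiments
#'
#' CW torque `tau_wrap` drives the cell into the wrapping mode; the motor
#' pauses at `P_I` for a duration `P_D`, then reverses to `tau_push`.
#'
#' @param P_I pause initiation time (s)
#' @param P_D pause duration (s)
#' @param total total run length (s)
#' @param tau_wrap,tau_push torques of the wrapping and push phases
#' @export
schedule_wrap_pause_push <- function(P_I, P_D, total,
                                     tau_wrap = -0.004, tau_push = 0.002) {
  stopifnot(P_I > 0, P_D > 0, total > P_I + P_D)
  motor_schedule(c(0, P_I, P_I + P_D), c(P_I, P_I + P_D, total),
                 c(tau_wrap, 0, tau_push),
                 label = c("wrapping", "pause", "push"))
}

#' Torque at a given time
#'
#' Segments are half-open `[t_start, t_end)`; the final right endpoint is
#' included.  Times outside the schedule are an error (no extrapolation).
#'
#' @param schedule a [motor_schedule()]
#' @param t time or vector of times (s)
#' @return torque values (g um^2/s^2)
#' @export
torque_at <- function(schedule, t) {
  stopifnot(inherits(schedule, "motor_schedule"))
  n <- length(schedule$t_start)
  out <- vapply(t, function(ti) {
    i <- which(ti >= schedule$t_start & ti < schedule$t_end)
    if (length(i) == 0) {
      if (abs(ti - schedule$t_end[n]) <= 1e-12) return(schedule$tau[n])
      stop("time ", ti, " is outside the motor schedule")
    }
    schedule$tau[i[1]]
  }, numeric(1))
  out
}

#' Motor ghost torque and its reaction on the body
#'
#' The motor applies the internal torque `N(-ds/2) = -tau E` at the ghost
#' point proximal to the first rod marker; through the staggered stencil the
#' flagellum (and hence the fluid) receives `+tau E`, and the same ghost
#' torque `-tau E` is applied to the cell body, which therefore
#' counter-rotates.  The pair sums to zero (action-reaction).
#'
#' @param E motor axis unit vector
#' @param tau applied torque (g um^2/s^2)
#' @return list with `N_ghost` (proximal boundary value of the internal
#'   torque) and `body_torque` (contribution to the external body torque)
#' @export
motor_ghost_torque <- function(E, tau) {
  E <- as.numeric(E)
  stopifnot(abs(sum(E^2) - 1) < 1e-8)
  list(N_ghost = -tau * E, body_torque = -tau * E)
}

#' Alignment feedback moment at the motor
#'
#' Restoring moment `ntilde = -K_m (E x D3(0))` that keeps the proximal
#' tangent aligned with the motor axis; `+ntilde` acts on the rod at the
#' motor marker and `-ntilde` on the cell body.
#'
#' @param E motor axis unit vector
#' @param D3_0 proximal rod tangent director
#' @param K_m alignment stiffness (g um^2/s^2)
#' @return the moment vector (g um^2/s^2)
#' @export
alignment_moment <- function(E, D3_0, K_m) {
  E <- as.numeric(E); D3_0 <- as.numeric(D3_0)
  -K_m * c(E[2] * D3_0[3] - E[3] * D3_0[2],
           E[3] * D3_0[1] - E[1] * D3_0[3],
           E[1] * D3_0[2] - E[2] * D3_0[1])
}

#' Clamp force pair tying the rod base to the motor pole
#'
#' A stiff spring realizes the attachment constraint `Yb_1 = X(0)`:
#' the rod's first marker receives `-K_c (X0 - Yb1)` and the body the
#' opposite force (applied at the pole, hence also a moment about the
#' centroid).  The pair sums to zero exactly.
#'
#' @param X0 position of the first rod marker
#' @param Yb1 position of the motor pole marker on the rigid body
#' @param K_c clamp stiffness (g/s^2)
#' @return list with `on_rod` and `on_body` forces
#' @export
clamp_forces <- function(X0, Yb1, K_c) {
  f <- -K_c * (as.numeric(X0) - as.numeric(Yb1))
  list(on_rod = f, on_body = -f)
}
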