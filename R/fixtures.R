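#' Synthetic trajectories with known ground truth
#'
#' Builds trajectory objects in the same layout as [run_simulation()]
#' output, with analytically known answers, so the analytics stage can be
#' tested without running the simulator.
#'
#' Kinds:
#' \describe{
#'   \item{`helix_line`}{a helical path about a known axis followed by a
#'     straight path at prescribed turn angle `theta` and longitude `phi`
#'     (degrees, in the fixed-frame convention of
#'     [turn_angle_longitude()]); truth in `attr(x, "truth")`.}
#'   \item{`constant_run`}{uniform translation with constant `v` and `E`.}
#'   \item{`wall_escape`}{monotone rising height.}
#'   \item{`wall_trapped`}{bounded oscillating height.}
#' }
#'
#' @param kind fixture kind
#' @param params named list overriding fixture parameters
#' @return a `lopho_trajectory` with attribute `truth`
#' @export
make_synthetic_trajectory <- function(kind = c("helix_line", "constant_run",
                                               "wall_escape", "wall_trapped"),
                                      params = list()) {
  kind <- match.arg(kind)
  p <- switch(kind,
    helix_line = modifyList(list(axis = c(0, 0, 1), radius = 0.4,
                                 period = 0.017, axial_speed = 4,
                                 n_periods = 10L, theta = 60, phi = 120,
                                 line_speed = 15, line_time = 0.1,
                                 dt = 5e-4), params),
    constant_run = modifyList(list(v = c(3, 0, 0), E = c(-1, 0, 0),
                                   duration = 0.1, dt = 1e-3), params),
    wall_escape = modifyList(list(h0 = 1, rate = 40, vx = 5, duration = 0.3,
                                  dt = 1e-3), params),
    wall_trapped = modifyList(list(h0 = 0.6, amp = 0.25, period = 0.05,
                                   vx = 5, duration = 0.3, dt = 1e-3), params))
  tr <- switch(kind,
    helix_line = .fx_helix_line(p),
    constant_run = .fx_constant(p),
    wall_escape = .fx_wall(p, escape = TRUE),
    wall_trapped = .fx_wall(p, escape = FALSE))
  tr
}

.traj_frame <- function(t, Tm, E, truth = NULL) {
  n <- length(t)
  df <- data.frame(t = t, Tx = Tm[, 1], Ty = Tm[, 2], Tz = Tm[, 3],
                   qw = 1, qx = 0, qy = 0, qz = 0,
                   Ex = E[, 1], Ey = E[, 2], Ez = E[, 3],
                   Vf = 0, phase_motor = 0, roll_body = 0, h = Tm[, 3],
                   net_force = 0, net_torque = 0, penalty_gap = 0,
                   clamp_gap = 0, min_steric = NA_real_)
  df$Vf <- forward_speed(df)
  structure(df, truth = truth, snapshots = list(), snapshot_times = numeric(0),
            class = c("lopho_trajectory", "data.frame"))
}

.fx_helix_line <- function(p) {
  ax <- p$axis / sqrt(sum(p$axis^2))
  fr <- .lab_frame(ax)
  th <- p$theta * pi / 180; ph <- p$phi * pi / 180
  post_dir <- cos(th) * ax + sin(th) * (cos(ph) * fr$x + sin(ph) * fr$y)
  t1 <- p$n_periods * p$period
  tt1 <- seq(0, t1, by = p$dt)
  ang <- 2 * pi * tt1 / p$period
  H <- outer(tt1 * p$axial_speed, ax) +
    p$radius * (outer(cos(ang) - 1, fr$x) + outer(sin(ang), fr$y))
  tt2 <- seq(p$dt, p$line_time, by = p$dt)
  L <- sweep(outer(tt2 * p$line_speed, post_dir), 2, H[nrow(H), ], "+")
  t <- c(tt1, t1 + tt2)
  Tm <- rbind(H, L)
  E <- matrix(rep(-ax, each = length(t)), ncol = 3)
  .traj_frame(t, Tm, E,
              truth = list(theta = p$theta, phi = p$phi, axis = ax,
                           pre = c(0, t1), post = c(t1 + 2 * p$dt, max(t)),
                           period = p$period))
}

.fx_constant <- function(p) {
  t <- seq(0, p$duration, by = p$dt)
  Tm <- outer(t, p$v)
  E <- matrix(rep(p$E / sqrt(sum(p$E^2)), each = length(t)), ncol = 3)
  .traj_frame(t, Tm, E, truth = list(v = p$v, E = p$E,
                                     Vf = -sum(p$v * p$E / sqrt(sum(p$E^2)))))
}

.fx_wall <- function(p, escape) {
  t <- seq(0, p$duration, by = p$dt)
  h <- if (escape) p$h0 + p$rate * t else
    p$h0 + p$amp * sin(2 * pi * t / p$period)
  Tm <- cbind(p$vx * t, 0, h)
  E <- matrix(rep(c(-1, 0, 0), each = length(t)), ncol = 3)
  .traj_frame(t, Tm, E, truth = list(escaping = escape))
}
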