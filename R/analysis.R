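#' Detect the steady segment of a trajectory
#'
#' Splits the record into consecutive windows and finds the earliest window
#' from which both the windowed mean forward speed and the windowed mean
#' motor rotation rate change by less than `tol` (relative) between
#' consecutive windows through the end of the run.
#'
#' @param traj a `lopho_trajectory`
#' @param window window length (s); default a tenth of the run
#' @param tol relative tolerance between consecutive windows
#' @return list with `start`, `end` (s) and the window means, or `NULL` if
#'   no steady segment exists
#' @export
detect_steady <- function(traj, window = NULL, tol = 0.05) {
  t <- traj$t
  span <- max(t) - min(t)
  if (is.null(window)) window <- span / 10
  if (span < 2 * window) stop("trajectory shorter than two windows")
  vf <- traj$Vf
  rate <- c(0, diff(traj$phase_motor) / diff(t))
  brk <- seq(min(t), max(t), by = window)
  if (length(brk) < 3) return(NULL)
  idx <- findInterval(t, brk, rightmost.closed = TRUE)
  mv <- tapply(vf, idx, mean)
  mr <- tapply(rate, idx, mean)
  nw <- length(mv)
  scale_v <- max(abs(mv), 1e-12)
  scale_r <- max(abs(mr), 1e-12)
  ok <- function(i) {
    dv <- abs(mv[i + 1] - mv[i]) / max(abs(mv[i]), abs(mv[i + 1]), 0.05 * scale_v)
    dr <- abs(mr[i + 1] - mr[i]) / max(abs(mr[i]), abs(mr[i + 1]), 0.05 * scale_r)
    dv < tol && dr < tol
  }
  stable <- vapply(seq_len(nw - 1), ok, logical(1))
  ## earliest window from which all later consecutive pairs are stable
  from <- which(rev(cumprod(rev(stable))) == 1)
  if (length(from) == 0) return(NULL)
  i0 <- from[1]
  list(start = brk[i0], end = max(t),
       Vf_mean = mean(vf[t >= brk[i0]]),
       rate_mean = mean(rate[t >= brk[i0]]))
}

#' Classify the swimming mode of a steady trajectory
#'
#' Operational rule: over the steady segment, compute the wrap fraction
#' `w` = fraction of flagellar markers (beyond the proximal exclusion zone)
#' that lie within a cylinder of radius `body_radius + 2 D` around the body
#' axis and axially overlap the body.  Under CW rotation (`tau < 0`),
#' `w >= wrap_threshold` is wrapping, otherwise pull; under CCW rotation
#' (`tau > 0`), `w >= wrap_threshold` is overwhirling, otherwise push.
#' The sign of the steady forward speed is recorded as a consistency
#' diagnostic (`push > 0`, `pull < 0`).
#'
#' @param traj a `lopho_trajectory` with rod snapshots
#' @param config the [sim_config()] of the run (defaults to the one stored
#'   in the trajectory)
#' @param steady result of [detect_steady()]; computed when `NULL`
#' @param wrap_threshold wrap-fraction threshold of the rule
#' @return a character label in `push`, `pull`, `wrapping`, `overwhirling`,
#'   `undetermined`, with attributes `wrap_fraction`, `Vf_mean`, `steady`
#' @export
classify_mode <- function(traj, config = attr(traj, "config"), steady = NULL,
                          wrap_threshold = 0.5) {
  if (is.null(steady)) {
    steady <- tryCatch(detect_steady(traj), error = function(e) NULL)
  }
  und <- structure("undetermined", wrap_fraction = NA_real_,
                   Vf_mean = NA_real_, steady = steady)
  if (is.null(steady)) return(und)
  snaps <- attr(traj, "snapshots")
  stimes <- attr(traj, "snapshot_times")
  use <- which(stimes >= steady$start)
  if (length(snaps) == 0 || length(use) == 0) return(und)
  tau <- torque_at(config$schedule, min(steady$end, (steady$start + steady$end) / 2))
  if (tau == 0) return(und)
  ## wrap fraction on the latest snapshots of the steady segment
  use <- use[max(1, length(use) - 2):length(use)]
  wf <- vapply(use, function(k) {
    .wrap_fraction(snaps[[k]], traj, stimes[k], config)
  }, numeric(1))
  w <- mean(wf)
  vf <- steady$Vf_mean
  lab <- if (tau < 0) {
    if (w >= wrap_threshold) "wrapping" else "pull"
  } else {
    if (w >= wrap_threshold) "overwhirling" else "push"
  }
  structure(lab, wrap_fraction = w, Vf_mean = vf, steady = steady)
}

.wrap_fraction <- function(snap, traj, time, config) {
  i <- which.min(abs(traj$t - time))
  E <- as.numeric(traj[i, c("Ex", "Ey", "Ez")])
  Tc <- as.numeric(traj[i, c("Tx", "Ty", "Tz")])
  axis <- -E  # from motor pole toward the opposite pole
  rel <- sweep(snap, 2, Tc)
  ax <- rel %*% axis
  rad <- sqrt(pmax(rowSums(rel^2) - ax^2, 0))
  hl <- config$body$body_length / 2
  rcyl <- config$body$body_radius + 2 * config$steric$D
  sref <- (seq_len(nrow(snap)) - 1) * config$helix$ds
  sel <- sref >= config$steric$L_prime
  inside <- rad[sel] <= rcyl & abs(ax[sel]) <= hl
  mean(inside)
}

#' Turn angle and longitude between two steady swimming segments
#'
#' The pre-switch direction is the axis of the (generally helical) path in
#' the pre segment: the principal axis of the centred positions, signed by
#' the net displacement.  The post direction is the normalized net
#' displacement of the post segment.  The turn angle is the angle between
#' the two; the longitude is the azimuth of the post direction in a fixed
#' frame whose polar axis is the pre direction and whose x-axis is the
#' projection of the lab x-axis (fallback y-axis when degenerate).
#'
#' @param traj a `lopho_trajectory`
#' @param pre,post time windows `c(t0, t1)` of the two steady segments; the
#'   pre window should span an integer number of rotation periods
#' @return named vector `c(theta, phi)` in degrees, `theta` in `[0, 180]`,
#'   `phi` in `[0, 360)`
#' @export
turn_angle_longitude <- function(traj, pre, post) {
  P <- as.matrix(traj[, c("Tx", "Ty", "Tz")])
  t <- traj$t
  ipre <- t >= pre[1] & t <= pre[2]
  ipost <- t >= post[1] & t <= post[2]
  if (sum(ipre) < 3 || sum(ipost) < 2) {
    stop("segments too short for direction estimates")
  }
  pre_dir <- .path_axis(P[ipre, , drop = FALSE])
  dpost <- P[max(which(ipost)), ] - P[min(which(ipost)), ]
  if (sqrt(sum(dpost^2)) < 1e-12) stop("post segment has no net displacement")
  post_dir <- dpost / sqrt(sum(dpost^2))
  theta <- acos(min(1, max(-1, sum(pre_dir * post_dir)))) * 180 / pi
  fr <- .lab_frame(pre_dir)
  phi <- atan2(sum(post_dir * fr$y), sum(post_dir * fr$x)) * 180 / pi
  if (phi < 0) phi <- phi + 360
  c(theta = theta, phi = phi)
}

## direction of a (possibly helical) path segment: the net displacement,
## which for an ideal helix over an integer number of periods equals the
## helix axis exactly (the principal axis of the positions degenerates when
## the coil radius exceeds the axial travel, as it does for slow wrapping
## paths)
.path_axis <- function(P) {
  v <- P[nrow(P), ] - P[1, ]
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("path segment has no net displacement")
  v / n
}

.lab_frame <- function(polar) {
  xl <- c(1, 0, 0)
  xp <- xl - polar * sum(xl * polar)
  if (sqrt(sum(xp^2)) < 1e-6) {
    xl <- c(0, 1, 0)
    xp <- xl - polar * sum(xl * polar)
  }
  xp <- xp / sqrt(sum(xp^2))
  yp <- c(polar[2] * xp[3] - polar[3] * xp[2],
          polar[3] * xp[1] - polar[1] * xp[3],
          polar[1] * xp[2] - polar[2] * xp[1])
  list(x = xp, y = yp)
}

#' Pause-mediated reorientation sweep
#'
#' Runs the wrapping-pause-push scenario over a grid of pause initiation
#' times `P_I^k = PI0 + dPI * k` and pause durations `P_D^j = PD0 + dPD * j`
#' and measures the turn angle and longitude of each event.  The reference
#' sweep uses `PI0 = 0.15 s`, `dPI = 0.0017 s` (k = 0..20, two flagellar
#' rotation periods) and `PD0 = 0.025 s`, `dPD = 0.005 s` (j = 0..12);
#' scaled-down grids are first-class citizens via the `k` and `j`
#' arguments.
#'
#' @param config base [sim_config()] (schedule is replaced per run)
#' @param k,j integer grid indices
#' @param PI0,dPI,PD0,dPD grid origin and spacing (s)
#' @param tau_wrap,tau_push phase torques (g um^2/s^2)
#' @param settle additional push time after the pause (s)
#' @param pre_span length of the pre-segment window before the pause (s)
#' @param post_frac final fraction of the run used as the post segment
#' @param verbose print progress
#' @return data frame with one row per event: `k`, `j`, `P_I`, `P_D`,
#'   `theta`, `phi`, `outcome`
#' @export
pause_sweep <- function(config, k = 0:20, j = 0:12,
                        PI0 = 0.15, dPI = 0.0017, PD0 = 0.025, dPD = 0.005,
                        tau_wrap = -0.004, tau_push = 0.002,
                        settle = 0.12, pre_span = 0.05, post_frac = 0.25,
                        verbose = FALSE) {
  grid <- expand.grid(k = k, j = j)
  out <- vector("list", nrow(grid))
  base_state <- initial_cell_state(config)
  for (i in seq_len(nrow(grid))) {
    PI <- PI0 + dPI * grid$k[i]
    PD <- PD0 + dPD * grid$j[i]
    cfg <- config
    cfg$schedule <- schedule_wrap_pause_push(PI, PD, PI + PD + settle,
                                             tau_wrap, tau_push)
    cfg$duration <- cfg$schedule$t_end[3]
    res <- tryCatch({
      traj <- run_simulation(cfg, state = base_state)
      tl <- turn_angle_longitude(traj, pre = c(PI - pre_span, PI),
                                 post = c(cfg$duration * (1 - post_frac) +
                                          post_frac * (PI + PD), cfg$duration))
      post <- traj[traj$t >= PI + PD, , drop = FALSE]
      attr(post, "config") <- cfg
      attr(post, "snapshots") <- attr(traj, "snapshots")
      attr(post, "snapshot_times") <- attr(traj, "snapshot_times")
      cls <- tryCatch(as.character(classify_mode(post, cfg)),
                      error = function(e) "undetermined")
      data.frame(k = grid$k[i], j = grid$j[i], P_I = PI, P_D = PD,
                 theta = tl["theta"], phi = tl["phi"], outcome = cls)
    }, error = function(e) {
      data.frame(k = grid$k[i], j = grid$j[i], P_I = PI, P_D = PD,
                 theta = NA_real_, phi = NA_real_,
                 outcome = paste0("error: ", conditionMessage(e)))
    })
    out[[i]] <- res
    if (verbose) message(sprintf("pause sweep %d/%d: k=%d j=%d -> %s",
                                 i, nrow(grid), grid$k[i], grid$j[i],
                                 res$outcome))
  }
  do.call(rbind, out)
}

#' Mode phase diagram over hook stiffness and applied torque
#'
#' Runs the constant-torque scenario on a grid of hook bending moduli and
#' torques, classifies each run and locates, per hook modulus, the critical
#' torque that separates push from overwhirling (CCW branch) and pull from
#' wrapping (CW branch).
#'
#' @param config base [sim_config()]
#' @param a_hook_values hook bending moduli (g um^3/s^2)
#' @param tau_values applied torques, both signs allowed (g um^2/s^2)
#' @param sim_time run length per cell (s)
#' @param verbose print progress
#' @return list with `cells` (data frame: `a_hook`, `tau`, `mode`,
#'   `Vf_mean`, `rate_mean`) and `thresholds` (data frame: `a_hook`,
#'   `tau_ccw`, `tau_cw`; `NA` when a branch has no transition inside the
#'   grid)
#' @export
phase_diagram <- function(config, a_hook_values, tau_values, sim_time = 0.08,
                          verbose = FALSE) {
  cells <- list()
  for (ah in a_hook_values) {
    for (tv in tau_values) {
      cfg <- config
      cfg$a_hook <- ah
      cfg$schedule <- schedule_constant(tv, sim_time)
      cfg$duration <- sim_time
      md <- tryCatch({
        traj <- run_simulation(cfg)
        cl <- classify_mode(traj, cfg)
        st <- attr(cl, "steady")
        data.frame(a_hook = ah, tau = tv, mode = as.character(cl),
                   Vf_mean = st$Vf_mean %||% NA_real_,
                   rate_mean = st$rate_mean %||% NA_real_)
      }, error = function(e) {
        data.frame(a_hook = ah, tau = tv, mode = "undetermined",
                   Vf_mean = NA_real_, rate_mean = NA_real_)
      })
      cells[[length(cells) + 1]] <- md
      if (verbose) message(sprintf("phase diagram a_hook=%.2g tau=%.3g -> %s",
                                   ah, tv, md$mode))
    }
  }
  cells <- do.call(rbind, cells)
  thr <- do.call(rbind, lapply(unique(cells$a_hook), function(ah) {
    cc <- cells[cells$a_hook == ah, ]
    ccw <- cc[cc$tau > 0, ][order(cc$tau[cc$tau > 0]), ]
    cw <- cc[cc$tau < 0, ][order(-cc$tau[cc$tau < 0]), ]  # increasing |tau|
    data.frame(a_hook = ah,
               tau_ccw = .threshold(ccw$tau, ccw$mode, "push", "overwhirling"),
               tau_cw = -.threshold(-cw$tau, cw$mode, "pull", "wrapping"))
  }))
  list(cells = cells, thresholds = thr)
}

## midpoint between the last grid point in mode `lo` and the first in `hi`
.threshold <- function(tau_abs, mode, lo, hi) {
  il <- which(mode == lo)
  ih <- which(mode == hi)
  if (length(il) == 0 || length(ih) == 0) return(NA_real_)
  if (min(ih) < max(il)) return(NA_real_)  # non-monotone labelling
  (tau_abs[max(il)] + tau_abs[min(ih)]) / 2
}

#' Classify a near-wall run as escaping or trapped
#'
#' Escaping if the final height exceeds `h_esc` and the mean height slope
#' over the final fraction of the run is positive; trapped otherwise.
#'
#' @param traj a `lopho_trajectory` of a wall run (with `h` recorded)
#' @param h_esc escape height (um); default twice the body length
#' @param final_frac fraction of the run used for the slope test
#' @return character label `"escaping"` or `"trapped"`, with attributes
#'   `h_end` and `dhdt`
#' @export
wall_escape <- function(traj, h_esc = NULL, final_frac = 0.2) {
  cfg <- attr(traj, "config")
  if (is.null(h_esc)) {
    h_esc <- 2 * (cfg$body$body_length %||% 2.4)
  }
  n <- nrow(traj)
  tail_idx <- traj$t >= (max(traj$t) - final_frac * (max(traj$t) - min(traj$t)))
  fit <- stats::lm(h ~ t, data = traj[tail_idx, ])
  dhdt <- unname(coef(fit)[2])
  lab <- if (traj$h[n] > h_esc && dhdt > 0) "escaping" else "trapped"
  structure(lab, h_end = traj$h[n], dhdt = dhdt)
}
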