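#' Build the initial cell state from a configuration
#'
#' Constructs the capsule mesh and the reference flagellum, attaches the
#' flagellum normally to the motor pole, applies the initial rotation about
#' the body's major axis and, for wall runs, lays the cell parallel to the
#' wall at height `h0`.
#'
#' @param config a [sim_config()]
#' @return object of class `cell_state`: rod arrays (`X`, `D1`, `D2`, `D3`),
#'   body arrays (`Z`, `Xb`, `T`, `Rot`), intrinsic strains, moduli and
#'   bookkeeping (accumulated motor phase and body roll, time)
#' @export
initial_cell_state <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  hx <- config$helix
  Z <- build_body_mesh(config$body)
  bl <- config$body$body_length
  ## construction frame: body axis along z, motor pole at +z, E_ref = +z
  curve <- build_reference_flagellum(hx)
  arc <- sum(curve$spacing)
  n_f <- hx$n_f %||% (round(arc / hx$ds) + 1)
  uni <- reparametrize_by_arclength(curve, n_f)
  ds <- mean(uni$spacing)
  triads <- initial_frame(uni)
  intr <- intrinsic_strain_twist(uni, triads)
  mod <- elastic_moduli(n_f - 1, ds, L_h = hx$L_h, a = config$a,
                        a_hook = config$a_hook, a3 = config$a3, b = config$b)
  ## place rod: reference mesh has motor pole at (0,0,bl/2) before rotation;
  ## build_body_mesh orients motor pole along -pole_axis
  Eref <- -config$body$pole_axis
  pole <- Eref * bl / 2
  Rpose <- .rotation_between(c(0, 0, 1), Eref)
  X <- sweep(uni$points %*% t(Rpose), 2, pole, "+")
  D1 <- triads$D1 %*% t(Rpose)
  D2 <- triads$D2 %*% t(Rpose)
  D3 <- triads$D3 %*% t(Rpose)

  ## initial pose of the whole cell
  spin <- config$initial_rotation_angle * pi / 180
  Rspin <- .axis_rotation(Eref, spin)
  Rot0 <- Rspin
  T0 <- c(0, 0, 0)
  if (config$wall_enabled) {
    ## lay the body axis parallel to the wall (along +x), centre at h0
    Rlay <- .rotation_between(Eref, c(1, 0, 0))
    Rot0 <- Rlay %*% Rspin
    T0 <- c(0, 0, config$h0)
  }
  X <- sweep(X %*% t(Rot0), 2, T0, "+")
  D1 <- D1 %*% t(Rot0); D2 <- D2 %*% t(Rot0); D3 <- D3 %*% t(Rot0)
  Xb <- sweep(Z %*% t(Rot0), 2, T0, "+")

  ## reference vectors perpendicular to E_ref for motor-phase bookkeeping
  r1 <- if (abs(Eref[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  r1 <- r1 - Eref * sum(r1 * Eref); r1 <- r1 / sqrt(sum(r1^2))
  r2 <- c(Eref[2] * r1[3] - Eref[3] * r1[2],
          Eref[3] * r1[1] - Eref[1] * r1[3],
          Eref[1] * r1[2] - Eref[2] * r1[1])

  structure(list(X = X, D1 = D1, D2 = D2, D3 = D3,
                 Z = unclass(Z)[, , drop = FALSE], Xb = Xb,
                 T = T0, Rot = Rot0,
                 ds = ds, n_f = n_f, sref = (seq_len(n_f) - 1) * ds,
                 Omega = intr$Omega, Gamma = intr$Gamma, moduli = mod,
                 Eref = Eref, ref1 = r1, ref2 = r2,
                 body_spacing = attr(Z, "spacing"),
                 motor_index = attr(Z, "motor_index"),
                 phase_motor = 0, roll_body = 0, t = 0),
            class = "cell_state")
}

.axis_rotation <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  vx <- rbind(c(0, -axis[3], axis[2]), c(axis[3], 0, -axis[1]),
              c(-axis[2], axis[1], 0))
  diag(3) + sin(angle) * vx + (1 - cos(angle)) * vx %*% vx
}

.pack <- function(state, config, dt) {
  epsb <- config$eps_b %||% (0.9 * state$body_spacing)
  rigid_tol <- config$rigid_tol %||%
    (1e-10 * config$K * config$body$body_radius * nrow(state$Z))
  list(X = state$X, D1 = state$D1, D2 = state$D2, D3 = state$D3,
       amod = state$moduli$a, bmod = state$moduli$b,
       Om = state$Omega, Gam = state$Gamma, sref = state$sref,
       Z = state$Z, Xb = state$Xb, Rot = state$Rot, T = state$T,
       Eref = state$Eref, ref1 = state$ref1, ref2 = state$ref2,
       ds = state$ds, eps_f = config$eps_f, eps_b = epsb,
       inv_alpha1 = ifelse(is.finite(config$alpha1), 1 / config$alpha1, 0),
       inv_alpha2 = ifelse(is.finite(config$alpha2), 1 / config$alpha2, 0),
       inv_beta = ifelse(is.finite(config$beta), 1 / config$beta, 0),
       K = config$K, K_m = config$K_m, K_c = config$K_c,
       C_rep = config$steric$C, D_rep = config$steric$D,
       L_prime = config$steric$L_prime,
       c_w = config$steric$c_w, D_w = config$steric$D_w,
       wall = config$wall_enabled, wall_spread = config$wall_spread,
       mu = config$mu, dt = dt, t0 = state$t,
       motor_index = state$motor_index,
       rigid_tol = rigid_tol, rigid_maxit = config$rigid_maxit,
       theta_c = config$fold_barrier %||% pi,
       self_rotlet = config$self_rotlet %||% TRUE, qseg = state$qseg %||% matrix(numeric(0), 0, 4),
       phase_motor = state$phase_motor, roll_body = state$roll_body,
       schedule = list(t_start = config$schedule$t_start,
                       t_end = config$schedule$t_end,
                       tau = config$schedule$tau,
                       ramp = config$tau_ramp %||% 0))
}

.rec_names <- c("t", "Tx", "Ty", "Tz", "qw", "qx", "qy", "qz",
                "Ex", "Ey", "Ez", "Vf", "phase_motor", "roll_body", "h",
                "net_force", "net_torque", "penalty_gap", "clamp_gap",
                "min_steric")

.update_state <- function(state, out, dt, nsteps) {
  state$X <- out$X; state$D1 <- out$D1; state$D2 <- out$D2; state$D3 <- out$D3
  state$Xb <- out$Xb; state$T <- out$T; state$Rot <- out$Rot
  state$phase_motor <- out$phase_motor; state$roll_body <- out$roll_body
  state$qseg <- out$qseg
  state$t <- state$t + dt * nsteps
  state
}

#' Advance the coupled system by one (or a few) time steps
#'
#' One explicit step: elastic, motor, steric and penalty forces are
#' assembled, spread to the fluid, the regularized velocity and angular
#' velocity fields are evaluated at all markers, markers and triads are
#' updated with their slip terms, and the rigid body configuration is
#' re-solved.
#'
#' @param state a `cell_state`
#' @param config a [sim_config()]
#' @param nsteps number of steps to take
#' @return the advanced `cell_state`, with the last record row as attribute
#'   `record`
#' @export
step_cell <- function(state, config, nsteps = 1L) {
  pack <- .pack(state, config, config$dt)
  out <- cpp_run(pack, as.integer(nsteps), as.integer(nsteps), 0L)
  if (out$status != 0) {
    stop("step failed at step ", out$fail_step, " (t=",
         format(state$t + out$fail_step * config$dt), "): ", out$fail_message)
  }
  rec <- out$records
  colnames(rec) <- .rec_names
  st <- .update_state(state, out, config$dt, nsteps)
  attr(st, "record") <- rec[nrow(rec), ]
  st
}

#' Run a full simulation
#'
#' Deterministic driver: advances the configured schedule from `t = 0` to
#' `duration`, recording body pose, motor axis, forward speed, motor phase,
#' body roll and diagnostics at the configured cadence, plus periodic rod
#' snapshots.  On a blow-up the run is retried once with half the time step
#' (if `auto_halve_dt`).
#'
#' @param config a [sim_config()]
#' @param state optional prepared initial state (default
#'   [initial_cell_state()])
#' @return a `lopho_trajectory`: data frame of records with attributes
#'   `config`, `snapshots`, `snapshot_times`, `final_state`
#' @export
run_simulation <- function(config, state = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(state)) state <- initial_cell_state(config)
  dt <- config$dt
  tries <- if (isTRUE(config$auto_halve_dt)) 2L else 1L
  for (k in seq_len(tries)) {
    nsteps <- ceiling((config$duration - state$t) / dt - 1e-9)
    rec_every <- max(1L, as.integer(round(config$record_every * config$dt / dt)))
    pack <- .pack(state, config, dt)
    out <- cpp_run(pack, as.integer(nsteps), rec_every,
                   as.integer(config$snap_every))
    if (out$status == 0) break
    if (k == tries) {
      stop("simulation blew up at t=", format(out$fail_step * dt), " s: ",
           out$fail_message, " (after dt halving)")
    }
    dt <- dt / 2
  }
  rec <- as.data.frame(out$records)
  names(rec) <- .rec_names
  final <- .update_state(state, out, dt, nsteps)
  structure(rec,
            config = config, dt_used = dt,
            snapshots = out$snapshots, snapshot_times = out$snapshot_times,
            final_state = final,
            class = c("lopho_trajectory", "data.frame"))
}

#' @export
print.lopho_trajectory <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<lopho_trajectory> %d samples over %.4g s\n",
              nrow(x), max(x$t) - min(x$t)))
  v <- x$Vf[-1]
  if (length(v)) {
    cat(sprintf("  forward speed: mean %.3g um/s (last third %.3g um/s)\n",
                mean(v), mean(v[seq(max(1, floor(2 * length(v) / 3)), length(v))])))
  }
  cat(sprintf("  motor turns: %.2f, body roll turns: %.2f\n",
              (x$phase_motor[nrow(x)] - x$phase_motor[1]) / (2 * pi),
              (x$roll_body[nrow(x)] - x$roll_body[1]) / (2 * pi)))
  invisible(x)
}

#' Forward swimming speed from a trajectory
#'
#' `V_f(t) = -dT/dt . E(t)`: the speed of the body centroid along the
#' direction from the motor pole to the opposite pole.  Centred differences
#' in the interior, one-sided at the ends.
#'
#' @param traj a `lopho_trajectory` (or data frame with `t`, `Tx..Tz`,
#'   `Ex..Ez`)
#' @return numeric vector of `V_f` values, one per sample
#' @export
forward_speed <- function(traj) {
  stopifnot(nrow(traj) >= 2)
  Tm <- as.matrix(traj[, c("Tx", "Ty", "Tz")])
  E <- as.matrix(traj[, c("Ex", "Ey", "Ez")])
  t <- traj$t
  n <- nrow(Tm)
  dT <- matrix(0, n, 3)
  dT[1, ] <- (Tm[2, ] - Tm[1, ]) / (t[2] - t[1])
  dT[n, ] <- (Tm[n, ] - Tm[n - 1, ]) / (t[n] - t[n - 1])
  if (n > 2) {
    dT[2:(n - 1), ] <- (Tm[3:n, ] - Tm[1:(n - 2), ]) / (t[3:n] - t[1:(n - 2)])
  }
  -rowSums(dT * E)
}
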