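#' Simulation configuration
#'
#' Collects all physical and numerical parameters of a run.  Units are
#' grams, micrometres and seconds throughout; with these units water has
#' viscosity `mu = 1e-6`.
#'
#' The geometric, elastic and motor defaults are the package's reference
#' parameter set for a Pseudomonas-putida-like cell (body about 1 um
#' diameter by 2.4 um length, left-handed filament of about 7 um contour
#' length, filament bending modulus `a = 0.003 g um^3/s^2`, hook modulus
#' `a/25`); the numerical defaults (marker spacings, blob widths, time
#' step) are a desk-scale resolution validated by the mode benchmarks.
#'
#' @param helix a [helix_spec()]
#' @param body a [body_spec()]
#' @param a,a_hook,a3,b elastic moduli, see [elastic_moduli()]
#' @param mu fluid viscosity (g/(um s))
#' @param eps_f blob width of flagellar sources (um)
#' @param eps_b blob width of body sources (um); default tied to the body
#'   mesh spacing
#' @param K penalty stiffness body markers (g/s^2)
#' @param K_c clamp stiffness at the motor pole (g/s^2)
#' @param K_m alignment feedback stiffness (g um^2/s^2)
#' @param steric a [steric_params()]
#' @param alpha1 translational drag of flagellar markers (per unit s)
#' @param alpha2 translational drag of body markers
#' @param beta rotational drag of the triads (g um/s); `Inf` disables the
#'   angular slip
#' @param schedule a [motor_schedule()]
#' @param dt time step (s)
#' @param duration run length (s); defaults to the schedule duration
#' @param wall_enabled simulate above a no-slip wall at z = 0
#' @param wall_spread also spread the wall repulsion to the fluid
#' @param h0 initial height of the body centre above the wall (um)
#' @param initial_rotation_angle rotation of the whole cell about its major
#'   axis before release (degrees)
#' @param record_every record a trajectory sample every this many steps
#' @param snap_every store a rod snapshot every this many records (0 = only
#'   implicit final state)
#' @param rigid_tol,rigid_maxit rigid-solve tolerance (absolute, in units of
#'   `K * body_radius * n_b`; `NULL` for 1e-10 relative) and iteration cap
#' @param tau_ramp motor torque blend-in time at schedule transitions (s);
#'   reversals of a real motor are not instantaneous, and the blend keeps
#'   the torque step resolvable at desk-scale marker spacings
#' @param fold_barrier maximum rotation angle between neighbouring triads
#'   (rad); a smooth stiffening diverging at this angle keeps hairpin folds
#'   distributed over several joints at coarse marker spacings
#' @param self_rotlet include a marker's own rotlet in the angular velocity
#'   rotating its triad (the default); when excluded, the roll drag of the
#'   filament is set by `beta` alone, which destabilizes the shortest twist
#'   modes -- kept as an experimental switch
#' @param auto_halve_dt on blow-up, retry once with half the time step
#' @return object of class `sim_config`
#' @export
sim_config <- function(helix = helix_spec(),
                       body = body_spec(),
                       a = 0.003, a_hook = a / 25, a3 = a,
                       b = c(0.5, 0.5, 0.5),
                       mu = 1e-6,
                       eps_f = 0.2, eps_b = NULL,
                       K = 1, K_c = 3, K_m = 0.3,
                       steric = steric_params(),
                       alpha1 = 2e-4, alpha2 = 2e-4, beta = 6e-6,
                       schedule = schedule_constant(0.002, 0.05),
                       dt = 1.25e-7, duration = NULL,
                       wall_enabled = FALSE, wall_spread = TRUE,
                       h0 = 1.0, initial_rotation_angle = 0,
                       record_every = 500L, snap_every = 10L,
                       rigid_tol = NULL, rigid_maxit = 50L,
                       tau_ramp = 0.004, fold_barrier = pi, self_rotlet = TRUE,
                       auto_halve_dt = TRUE) {
  stopifnot(inherits(helix, "helix_spec"), inherits(body, "body_spec"),
            inherits(schedule, "motor_schedule"), dt > 0, mu > 0,
            all(c(a, a_hook, a3, b, K, K_c, K_m, alpha1, alpha2, beta) > 0),
            eps_f > 0)
  if (is.null(duration)) duration <- schedule$t_end[length(schedule$t_end)]
  if (wall_enabled && h0 <= steric$D_w) {
    stop("h0 must exceed the minimum wall distance D_w")
  }
  cfg <- list(helix = helix, body = body, a = a, a_hook = a_hook, a3 = a3,
              b = b, mu = mu, eps_f = eps_f, eps_b = eps_b, K = K, K_c = K_c,
              K_m = K_m, steric = steric, alpha1 = alpha1, alpha2 = alpha2,
              beta = beta, schedule = schedule, dt = dt, duration = duration,
              wall_enabled = wall_enabled, wall_spread = wall_spread, h0 = h0,
              initial_rotation_angle = initial_rotation_angle,
              record_every = as.integer(record_every),
              snap_every = as.integer(snap_every),
              rigid_tol = rigid_tol, rigid_maxit = as.integer(rigid_maxit),
              tau_ramp = tau_ramp, fold_barrier = fold_barrier,
              self_rotlet = self_rotlet,
              auto_halve_dt = auto_halve_dt)
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  flagellum: R=%.3g um, pitch=%.3g um, L_h=%.3g, L_f=%.3g, ds=%.3g\n",
              x$helix$radius, x$helix$pitch, x$helix$L_h, x$helix$L_f, x$helix$ds))
  cat(sprintf("  body: %.3g x %.3g um, ~%d markers\n",
              x$body$body_length, 2 * x$body$body_radius, x$body$n_b))
  cat(sprintf("  moduli: a=%.3g, a_hook=%.3g, a3=%.3g; b=(%s)\n",
              x$a, x$a_hook, x$a3, paste(signif(x$b, 3), collapse = ", ")))
  cat(sprintf("  fluid: mu=%.3g, eps_f=%.3g, eps_b=%s, wall=%s\n",
              x$mu, x$eps_f, ifelse(is.null(x$eps_b), "auto", format(x$eps_b)),
              x$wall_enabled))
  cat(sprintf("  schedule: %d segment(s), duration %.4g s, dt=%.3g s\n",
              length(x$schedule$tau), x$duration, x$dt))
  invisible(x)
}
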