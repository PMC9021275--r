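#' Regularization blob (cut-off function)
#'
#' `psi_eps(r) = 15 eps^4 / (8 pi (r^2 + eps^2)^(7/2))`, a smooth
#' approximate delta function with unit integral over R^3.  All velocity
#' and angular-velocity kernels in the package are the exact Stokes
#' solutions for forces and torques smeared by this blob.
#'
#' @param r distances (um), `r >= 0`
#' @param eps regularization length (um)
#' @return blob density values (1/um^3)
#' @export
blob_value <- function(r, eps) {
  stopifnot(eps > 0, all(r >= 0))
  cpp_blob_value(as.numeric(r), eps)
}

#' Force system acting on the fluid
#'
#' A collection of regularized point forces and point torques with their
#' positions, per-source regularization lengths and the fluid viscosity.
#'
#' @param positions source positions (n x 3, um)
#' @param forces point forces (n x 3, g um/s^2); zero if omitted
#' @param torques point torques (n x 3, g um^2/s^2); zero if omitted
#' @param eps regularization length(s), scalar or per source (um)
#' @param mu dynamic viscosity (g/(um s))
#' @return object of class `force_system`
#' @export
force_system <- function(positions, forces = NULL, torques = NULL,
                         eps, mu = 1e-6) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  zero <- matrix(0, n, 3)
  forces <- if (is.null(forces)) zero else as.matrix(forces)
  torques <- if (is.null(torques)) zero else as.matrix(torques)
  stopifnot(nrow(forces) == n, nrow(torques) == n, mu > 0, all(eps > 0),
            all(is.finite(positions)), all(is.finite(forces)),
            all(is.finite(torques)))
  eps <- rep_len(as.numeric(eps), n)
  structure(list(positions = positions, forces = forces, torques = torques,
                 eps = eps, mu = mu), class = "force_system")
}

#' Assemble the fluid force system of the immersed cell
#'
#' Collects the regularized sources the cell applies to the fluid: at the
#' flagellar markers the negated force and torque densities times `ds`
#' together with the steric repulsion acting on the rod; at the body
#' markers the negated penalty forces together with the steric reaction.
#' The steric pair forces enter in action-reaction pairs, so their net
#' momentum contribution is exactly zero.
#'
#' @param rod_x flagellar marker positions (n_f x 3)
#' @param densities list with `f`, `n` from [force_torque_densities()]
#'   (including any motor/clamp contributions already folded in)
#' @param body_x body marker positions (n_b x 3)
#' @param penalty penalty forces `Fb` from [penalty_forces()]
#' @param steric optional result of [body_flagellum_repulsion()]
#' @param ds flagellar marker spacing (um)
#' @param eps_f,eps_b regularization lengths for rod and body sources (um)
#' @param mu viscosity (g/(um s))
#' @return a [force_system()]
#' @export
assemble_force_system <- function(rod_x, densities, body_x, penalty,
                                  steric = NULL, ds, eps_f, eps_b, mu = 1e-6) {
  rod_x <- as.matrix(rod_x); body_x <- as.matrix(body_x)
  nf <- nrow(rod_x); nb <- nrow(body_x)
  if (nrow(densities$f) != nf) stop("rod density/marker count mismatch")
  if (nrow(penalty) != nb) stop("penalty force/body marker count mismatch")
  srod <- if (is.null(steric)) matrix(0, nf, 3) else steric$rod
  sbody <- if (is.null(steric)) matrix(0, nb, 3) else steric$body
  rodF <- (-densities$f + srod) * ds
  rodT <- -densities$n * ds
  bodyF <- -unclass(penalty) + sbody
  force_system(rbind(rod_x, body_x),
               forces = rbind(rodF, bodyF),
               torques = rbind(rodT, matrix(0, nb, 3)),
               eps = c(rep(eps_f, nf), rep(eps_b, nb)), mu = mu)
}

#' Velocity field of a regularized force system
#'
#' Exact Stokes velocity for the blob-regularized forcing
#' `sum F psi_eps(x - X) + (1/2) curl sum T psi_eps(x - X)`, evaluated at
#' arbitrary points (finite everywhere, including at the sources).
#'
#' @param points evaluation points (m x 3, um)
#' @param system a [force_system()]
#' @param wall if `TRUE`, add the exact image system enforcing `u = 0` on
#'   the plane `z = 0`; all sources and points must then have `z > 0`
#' @return velocity matrix (m x 3, um/s)
#' @export
velocity_at <- function(points, system, wall = FALSE) {
  points <- as.matrix(points)
  if (wall) .check_above_wall(points, system)
  cpp_fluid_fields(points, system$positions, system$forces, system$torques,
                   system$eps, system$mu, wall, FALSE)$u
}

#' Angular velocity field `w = (1/2) curl u`
#'
#' @inheritParams velocity_at
#' @return angular velocity matrix (m x 3, rad/s)
#' @export
angular_velocity_at <- function(points, system, wall = FALSE) {
  points <- as.matrix(points)
  if (wall) .check_above_wall(points, system)
  cpp_fluid_fields(points, system$positions, system$forces, system$torques,
                   system$eps, system$mu, wall, TRUE)$w
}

#' Velocity and angular velocity above a no-slip plane wall
#'
#' Adds, for every source, an image system of singular elements below the
#' plane (placed at depth `sqrt(h^2 + eps^2)`) whose combined field cancels
#' the regularized free-space field exactly on `z = 0`.
#'
#' @inheritParams velocity_at
#' @return list with matrices `u` and `w`
#' @export
wall_corrected_fields <- function(points, system) {
  points <- as.matrix(points)
  .check_above_wall(points, system)
  res <- cpp_fluid_fields(points, system$positions, system$forces,
                          system$torques, system$eps, system$mu, TRUE, TRUE)
  list(u = res$u, w = res$w)
}

.check_above_wall <- function(points, system) {
  if (any(system$positions[, 3] <= 0)) {
    stop("wall correction requires all sources strictly above the plane z = 0")
  }
  invisible(TRUE)
}
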