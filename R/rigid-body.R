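#' Rigid body state of the cell
#'
#' Two Lagrangian descriptions of the body surface are kept: the fluid-side
#' markers `Xb`, which move with the flow, and the rigid configuration
#' `Yb_i = T + Rot Z_i` reconstructed from the reference markers `Z`
#' (which sum to zero).  Marker pairs are tied by stiff springs of constant
#' `K` (penalty method).
#'
#' @param Z reference markers (n_b x 3), summing to zero
#' @param T centroid (length 3)
#' @param Rot 3 x 3 proper rotation
#' @param Xb fluid-side markers (n_b x 3); defaults to the rigid positions
#' @param K penalty stiffness (g/s^2)
#' @param motor_index index of the motor pole marker
#' @return object of class `rigid_body_state`
#' @export
rigid_body_state <- function(Z, T = c(0, 0, 0), Rot = diag(3), Xb = NULL,
                             K = 0.3, motor_index = attr(Z, "motor_index") %||% 1L) {
  Z <- as.matrix(Z)
  if (max(abs(colSums(Z))) > 1e-9) stop("reference markers Z must sum to zero")
  if (max(abs(crossprod(Rot) - diag(3))) > 1e-10 || det(Rot) < 0) {
    stop("Rot must be a proper rotation")
  }
  Yb <- sweep(Z %*% t(Rot), 2, T, "+")
  if (is.null(Xb)) Xb <- Yb
  structure(list(Z = Z, T = as.numeric(T), Rot = Rot, Xb = as.matrix(Xb),
                 K = K, motor_index = as.integer(motor_index)),
            class = "rigid_body_state")
}

#' Penalty spring forces between fluid-side and rigid markers
#'
#' `Fb_i = K (Xb_i - Yb_i)` acts on the rigid configuration; the negated
#' forces `-Fb_i` are the body forces applied to the fluid (returned as the
#' `fluid` attribute).
#'
#' @param state a [rigid_body_state()]
#' @return matrix of forces (n_b x 3) with attribute `fluid = -forces`
#' @export
penalty_forces <- function(state) {
  stopifnot(inherits(state, "rigid_body_state"))
  Yb <- sweep(state$Z %*% t(state$Rot), 2, state$T, "+")
  Fb <- state$K * (state$Xb - Yb)
  attr(Fb, "fluid") <- -Fb
  Fb
}

#' Solve the rigid body balance for centroid and rotation
#'
#' Solves `0 = fb + sum_i K(Xb_i - T - Rot Z_i)` and the corresponding
#' torque balance about the centroid for `T` (closed form) and `Rot`
#' (Newton iteration on an incremental rotation vector, warm-started).
#'
#' @param Xb fluid-side markers (n_b x 3)
#' @param loads list with `fb` (net external force) and `nb` (net external
#'   torque about the centroid), both length 3; zero by default
#' @param Z reference markers
#' @param K penalty stiffness
#' @param warm_start list with `T` and `Rot` starting guess
#' @param tol absolute tolerance on the torque-balance residual; default
#'   `1e-10 * K * n_b * |Z|_max`
#' @param maxit maximum Newton iterations
#' @return list with `T`, `Rot`, `iterations`, `force_residual`,
#'   `torque_residual`
#' @export
solve_rigid_configuration <- function(Xb, loads = list(fb = c(0, 0, 0), nb = c(0, 0, 0)),
                                      Z, K, warm_start = list(T = colMeans(Xb), Rot = diag(3)),
                                      tol = NULL, maxit = 50) {
  Xb <- as.matrix(Xb); Z <- as.matrix(Z)
  stopifnot(nrow(Xb) == nrow(Z))
  if (max(abs(colSums(Z))) > 1e-9) stop("reference markers Z must sum to zero")
  scale <- max(sqrt(rowSums(Z^2)))
  if (is.null(tol)) tol <- 1e-10 * K * nrow(Z) * max(scale, 1e-12)
  out <- cpp_rigid_solve(Xb, Z, K, as.numeric(loads$fb), as.numeric(loads$nb),
                         warm_start$Rot, tol, as.integer(maxit))
  if (out$iterations < 0) {
    stop("rigid body solve did not converge in ", maxit,
         " iterations; the time step may be too large or K too stiff")
  }
  out
}

#' Motor axis: outward surface normal at the motor pole
#'
#' @param state a [rigid_body_state()]
#' @param spec the [body_spec()] used to build the mesh
#' @return unit vector `E = Rot %*% E_ref` where `E_ref = -pole_axis` is the
#'   outward capsule normal at the motor pole in the reference frame
#' @export
motor_normal <- function(state, spec) {
  stopifnot(inherits(state, "rigid_body_state"), inherits(spec, "body_spec"))
  E <- as.numeric(state$Rot %*% (-spec$pole_axis))
  E / sqrt(sum(E^2))
}
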