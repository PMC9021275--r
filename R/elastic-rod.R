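#' Rod state: centreline markers and director triads
#'
#' @param X marker positions (n x 3, um)
#' @param D1,D2,D3 orthonormal director triads per marker (n x 3)
#' @param ds Lagrangian marker spacing (um)
#' @return an object of class `rod_state`
#' @export
rod_state <- function(X, D1, D2, D3, ds) {
  X <- as.matrix(X); D1 <- as.matrix(D1); D2 <- as.matrix(D2); D3 <- as.matrix(D3)
  n <- nrow(X)
  stopifnot(nrow(D1) == n, nrow(D2) == n, nrow(D3) == n, ds > 0)
  err <- max(abs(rowSums(D1 * D1) - 1), abs(rowSums(D2 * D2) - 1),
             abs(rowSums(D3 * D3) - 1), abs(rowSums(D1 * D2)),
             abs(rowSums(D1 * D3)), abs(rowSums(D2 * D3)))
  if (err > 1e-8) stop("rod_state: triads are not orthonormal (max deviation ",
                       format(err), ")")
  structure(list(X = X, D1 = D1, D2 = D2, D3 = D3, ds = ds, n = n),
            class = "rod_state")
}

#' Elastic moduli of the flagellum, per segment
#'
#' Bending moduli `a1 = a2` take the filament value `a` except on the hook
#' (arc length below `L_h` from the motor), where the softer `a_hook`
#' applies; the hook compliance controls the buckling transitions between
#' swimming modes.  The twist modulus `a3` is uniform.  The `b` moduli are
#' stiff penalties keeping the rod nearly inextensible and unshearable.
#'
#' @param n_seg number of segments (markers minus one)
#' @param ds segment spacing (um)
#' @param L_h hook arc length (um); segments with midpoint below `L_h` use
#'   hook bending moduli
#' @param a filament bending modulus (g um^3/s^2)
#' @param a_hook hook bending modulus (g um^3/s^2), default `a/25`
#' @param a3 twist modulus (g um^3/s^2)
#' @param b shear/stretch moduli, length-3 (g um/s^2)
#' @return object of class `elastic_moduli`: matrices `a`, `b` (n_seg x 3)
#'   and logical `hook_mask`
#' @export
elastic_moduli <- function(n_seg, ds, L_h = 0.2, a = 0.003, a_hook = a / 25,
                           a3 = a, b = c(0.5, 0.5, 0.5)) {
  stopifnot(n_seg >= 1, all(c(a, a_hook, a3, b) > 0))
  mids <- (seq_len(n_seg) - 0.5) * ds
  hook <- mids < L_h
  amat <- cbind(ifelse(hook, a_hook, a), ifelse(hook, a_hook, a), a3)
  bmat <- matrix(b, n_seg, 3, byrow = TRUE)
  structure(list(a = amat, b = bmat, hook_mask = hook, L_h = L_h),
            class = "elastic_moduli")
}

.omega_mats <- function(Omega, n_seg) {
  if (is.list(Omega)) {
    Om <- Omega$Omega; Gam <- Omega$Gamma
  } else {
    Om <- Omega; Gam <- NULL
  }
  if (is.null(Gam)) Gam <- cbind(0 * Om[, 1], 0 * Om[, 2], 0 * Om[, 3] + 1)
  stopifnot(nrow(Om) == n_seg, nrow(Gam) == n_seg)
  list(Om = as.matrix(Om), Gam = as.matrix(Gam))
}

#' Internal force and torque resultants of the rod
#'
#' Evaluates the constitutive relations at segment midpoints: the internal
#' force `F = sum_i b_i (D^i . X_s - Gamma_i) D^i` and internal torque
#' `N = sum_i a_i (strain_i - Omega_i) D^i`, with triads interpolated to the
#' midpoints by the half-rotation between neighbouring triads.
#'
#' @param state a [rod_state()]
#' @param moduli an [elastic_moduli()]
#' @param Omega intrinsic strains: result of [intrinsic_strain_twist()]
#'   (list with `Omega`, `Gamma`) or a plain `n-1 x 3` matrix of intrinsic
#'   curvature/twist (then `Gamma = (0,0,1)`)
#' @return list with matrices `F`, `N` (`n-1` x 3) and the measured
#'   `strain` (`n-1` x 6: three curvature/twist, three shear/stretch)
#' @export
internal_resultants <- function(state, moduli, Omega) {
  stopifnot(inherits(state, "rod_state"))
  og <- .omega_mats(Omega, state$n - 1)
  res <- cpp_rod_resultants(state$X, state$D1, state$D2, state$D3, state$ds,
                            moduli$a, moduli$b, og$Om, og$Gam, pi)
  res[c("F", "N", "strain")]
}

#' Force and torque densities at the rod markers
#'
#' Staggered differences of the half-point resultants:
#' `f = -dF/ds`, `n = -dN/ds - X_s x F`.  The distal end is free
#' (`F = N = 0` beyond the last marker); at the proximal end the motor ghost
#' values close the stencil (see [motor_ghost_torque()]).
#'
#' The densities follow the holding-force convention of the balance
#' equations: `f` equals plus the gradient of the elastic energy per `ds`,
#' the force the rod applies to the fluid is `-f`, and the slip velocity of
#' a marker is `-(1/alpha1) f`.
#'
#' @param res resultants from [internal_resultants()]
#' @param state a [rod_state()]
#' @param N_ghost proximal ghost internal torque (motor), length 3
#' @param F_ghost proximal ghost internal force, length 3
#' @return list with matrices `f`, `n` (n x 3)
#' @export
force_torque_densities <- function(res, state, N_ghost = c(0, 0, 0),
                                   F_ghost = c(0, 0, 0)) {
  stopifnot(inherits(state, "rod_state"))
  cpp_rod_densities(res$F, res$N, state$X, state$ds,
                    as.numeric(F_ghost), as.numeric(N_ghost))
}

#' Elastic energy of the rod
#'
#' Quadratic form in the deviations of the discrete strain invariants from
#' their intrinsic values; zero on the reference configuration and
#' non-negative everywhere.
#'
#' @inheritParams internal_resultants
#' @return scalar energy (g um^2/s^2)
#' @export
rod_energy <- function(state, moduli, Omega) {
  stopifnot(inherits(state, "rod_state"))
  og <- .omega_mats(Omega, state$n - 1)
  cpp_rod_energy(state$X, state$D1, state$D2, state$D3, state$ds,
                 moduli$a, moduli$b, og$Om, og$Gam, pi)
}
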