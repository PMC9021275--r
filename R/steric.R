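#' Steric interaction parameters
#'
#' Short-range linear repulsions preventing flagellum-body contact and
#' cell-wall contact.  The body-flagellum force has magnitude
#' `C * max(1 - d/D, 0)` per unit arc length and is switched off for the
#' proximal part of the rod (`s < L_prime`), which necessarily passes close
#' to the motor pole.
#'
#' @param C body-flagellum stiffness (g/s^2)
#' @param D minimum allowed body-flagellum distance (um)
#' @param L_prime proximal exclusion arc length (um)
#' @param c_w wall stiffness (g/s^2)
#' @param D_w minimum allowed wall distance (um)
#' @return object of class `steric_params`
#' @export
steric_params <- function(C = 1, D = 0.15, L_prime = 0.4545,
                          c_w = 2, D_w = 0.09) {
  stopifnot(C > 0, D > 0, L_prime > 0, c_w > 0, D_w > 0)
  structure(list(C = C, D = D, L_prime = L_prime, c_w = c_w, D_w = D_w),
            class = "steric_params")
}

#' Repulsive forces between the flagellum and the cell body
#'
#' For every (rod marker, body marker) pair closer than `D`, a repulsive
#' force of magnitude `C * max(1 - d/D, 0)` per unit arc length acts on the
#' rod marker, directed from the body marker toward the rod marker; the
#' opposite point force (weighted by `ds`) acts on the body marker.  Rod
#' markers with arc coordinate `s < L_prime` are excluded.
#'
#' @param X rod marker positions (n_f x 3)
#' @param Xb body marker positions (n_b x 3)
#' @param params a [steric_params()]
#' @param s arc coordinates of the rod markers (um); default `(0:(n_f-1)) * ds`
#' @param ds rod marker spacing, used for the body-side reaction weights
#' @return list with `rod` (force per unit s on each rod marker, n_f x 3),
#'   `body` (point reaction on each body marker, n_b x 3) and
#'   `min_distance` over the active pairs
#' @export
body_flagellum_repulsion <- function(X, Xb, params, s = NULL, ds = NULL) {
  X <- as.matrix(X); Xb <- as.matrix(Xb)
  nf <- nrow(X); nb <- nrow(Xb)
  if (is.null(ds)) ds <- 1
  if (is.null(s)) s <- (seq_len(nf) - 1) * ds
  rod <- matrix(0, nf, 3)
  body <- matrix(0, nb, 3)
  act <- which(s >= params$L_prime)
  mind <- Inf
  for (j in act) {
    dv <- sweep(Xb, 2, X[j, ], "-")      # body -> rod is -dv
    d <- sqrt(rowSums(dv^2))
    if (any(d < 1e-12)) stop("coincident rod/body markers (distance 0): the configuration has blown up")
    mind <- min(mind, min(d))
    hit <- which(d < params$D)
    if (length(hit) == 0) next
    mag <- params$C * (1 - d[hit] / params$D)
    dir <- -dv[hit, , drop = FALSE] / d[hit]
    pf <- dir * mag
    rod[j, ] <- rod[j, ] + colSums(pf)
    body[hit, ] <- body[hit, ] - pf * ds
  }
  list(rod = rod, body = body, min_distance = mind)
}

#' Repulsive force from a plane wall at z = 0
#'
#' `f_w = c_w * max(1 - z/D_w, 0) e_z` for any marker with height
#' `z < D_w`; always directed along +z, never attractive.
#'
#' @param positions marker positions (n x 3)
#' @param params a [steric_params()]
#' @return force matrix (n x 3)
#' @export
wall_repulsion <- function(positions, params) {
  positions <- as.matrix(positions)
  z <- positions[, 3]
  mag <- params$c_w * pmax(1 - z / params$D_w, 0)
  f <- cbind(0, 0, mag)
  dimnames(f) <- NULL
  f
}
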