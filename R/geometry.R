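#' Specification of the reference flagellum
#'
#' The reference flagellum is a straight hook of length `L_h` continued by a
#' left-handed helical filament whose radius grows from zero with the
#' envelope `r(s) = R (1 - exp(-c (s - L_h)^2))`.  In the axial
#' parameterization the centreline is
#' `X0(s) = (r(s) cos(k s), r(s) sin(k s), s)` for a right-handed helix; a
#' left-handed filament (the default) mirrors the sign of the angular
#' coordinate.  Before use the curve is re-sampled into markers with equal
#' consecutive spacing (see [reparametrize_by_arclength()]).
#'
#' @param radius helix radius R (um)
#' @param pitch axial rise per turn (um); exactly one of `pitch`, `k`
#' @param k wave number (rad/um), alternative to `pitch` (`pitch = 2*pi/k`)
#' @param L_h hook length (um)
#' @param L_f filament length along the helix axis (um)
#' @param c envelope growth rate (1/um^2)
#' @param ds target marker spacing after arc-length reparametrization (um)
#' @param n_f number of flagellar markers; derived from `ds` when `NULL`
#' @param left_handed logical; handedness of the filament
#' @return an object of class `helix_spec`
#' @export
helix_spec <- function(radius = 0.35, pitch = NULL, k = NULL,
                       L_h = 0.2, L_f = 4.2, c = 2,
                       ds = 0.2, n_f = NULL, left_handed = TRUE) {
  if (is.null(pitch) && is.null(k)) pitch <- 1.76
  if (is.null(k)) k <- 2 * pi / pitch
  if (is.null(pitch)) pitch <- 2 * pi / k
  if (abs(pitch * k - 2 * pi) > 1e-8) {
    stop("pitch and k are inconsistent: pitch must equal 2*pi/k")
  }
  if (radius < 0 || L_h <= 0 || L_f <= 0 || c <= 0 || ds <= 0) {
    stop("invalid helix specification: radius, lengths, c and ds must be positive")
  }
  if (!is.null(n_f) && n_f < 3) stop("n_f must be at least 3")
  structure(list(radius = radius, pitch = pitch, k = k, L_h = L_h, L_f = L_f,
                 c = c, ds = ds, n_f = n_f, left_handed = left_handed),
            class = "helix_spec")
}

#' Specification of the capsule-shaped cell body
#'
#' The cell body is a spherocylinder (capsule) of pole-to-pole length
#' `body_length` and radius `body_radius`, discretized by quasi-uniform
#' surface markers.  The marker with index `motor_index` (always 1) is the
#' pole point on the motor side; the outward surface normal there is the
#' motor axis in the reference frame.
#'
#' @param body_length pole-to-pole length (um)
#' @param body_radius capsule radius (um)
#' @param n_b target number of surface markers (the tiling may use a nearby
#'   count; the realized count is reported by [build_body_mesh()])
#' @param pole_axis unit vector of the reference major axis; the motor pole
#'   lies on the `-pole_axis` side
#' @return an object of class `body_spec`
#' @export
body_spec <- function(body_length = 2.4, body_radius = 0.5, n_b = 70,
                      pole_axis = c(0, 0, -1)) {
  if (body_length <= 2 * body_radius) {
    stop("body_length must exceed the diameter (capsule geometry)")
  }
  if (n_b < 6) stop("n_b must be at least 6")
  pole_axis <- pole_axis / sqrt(sum(pole_axis^2))
  structure(list(body_length = body_length, body_radius = body_radius,
                 n_b = n_b, pole_axis = pole_axis, motor_index = 1L),
            class = "body_spec")
}

#' Build the reference flagellum centreline
#'
#' Evaluates the analytic reference curve at the given axial stations
#' (default: a dense uniform grid suitable for subsequent arc-length
#' reparametrization).  The helical radius is identically zero on the hook.
#'
#' @param spec a [helix_spec()]
#' @param s axial stations in `[0, L_h + L_f]`; default dense grid
#' @return a `reference_curve`: list with `points` (n x 3) and `spacing`
#'   (consecutive euclidean distances)
#' @export
build_reference_flagellum <- function(spec, s = NULL) {
  stopifnot(inherits(spec, "helix_spec"))
  L <- spec$L_h + spec$L_f
  if (is.null(s)) s <- seq(0, L, length.out = 8001)
  if (any(s < -1e-12 | s > L + 1e-12)) stop("s outside [0, L_h + L_f]")
  r <- ifelse(s <= spec$L_h, 0,
              spec$radius * (1 - exp(-spec$c * (s - spec$L_h)^2)))
  ## left-handed: the angular coordinate decreases with s
  hand <- if (spec$left_handed) -1 else 1
  pts <- cbind(r * cos(spec$k * s), hand * r * sin(spec$k * s), s)
  reference_curve(pts)
}

#' @rdname build_reference_flagellum
#' @param points ordered 3-d positions (n x 3 matrix)
#' @export
reference_curve <- function(points) {
  points <- unname(as.matrix(points))
  if (is.null(dim(points)) || ncol(points) != 3) {
    points <- matrix(points, ncol = 3)
  }
  d <- if (nrow(points) < 2) numeric(0) else
    sqrt(rowSums((points[-1, , drop = FALSE] -
                  points[-nrow(points), , drop = FALSE])^2))
  structure(list(points = points, spacing = d), class = "reference_curve")
}

#' Reparametrize a curve by arc length
#'
#' Re-samples a polyline into `n_f` markers whose consecutive euclidean
#' distances are all equal (sphere-marching along the polyline, with the
#' common spacing adjusted by bisection so that both endpoints are
#' preserved).  This realizes the "equally spaced points along the curve"
#' discretization required by the rod model.
#'
#' @param curve a `reference_curve`
#' @param n_f number of output markers
#' @return a `reference_curve` with `n_f` points and uniform spacing
#' @export
reparametrize_by_arclength <- function(curve, n_f) {
  stopifnot(inherits(curve, "reference_curve"), n_f >= 2)
  P <- curve$points
  if (sum(curve$spacing) <= 0) stop("degenerate (zero-length) curve")
  arc <- c(0, cumsum(curve$spacing))
  Ltot <- arc[length(arc)]
  nseg <- n_f - 1
  ## end-to-end residual after marching n_f-1 spheres of radius delta
  march <- function(delta) {
    x <- P[1, ]
    idx <- 1L
    pts <- matrix(NA_real_, n_f, 3)
    pts[1, ] <- x
    for (m in seq_len(nseg)) {
      repeat {
        if (idx >= nrow(P)) return(list(short = TRUE, pts = pts, last = m))
        ## find intersection of segment [P[idx], P[idx+1]] with sphere
        a <- P[idx, ]; b <- P[idx + 1, ]
        ab <- b - a
        ## solve |a + t ab - x| = delta for t in (t0, 1]
        A <- sum(ab^2); B <- 2 * sum(ab * (a - x)); C <- sum((a - x)^2) - delta^2
        disc <- B^2 - 4 * A * C
        t <- if (disc >= 0) (-B + sqrt(disc)) / (2 * A) else 2
        if (t >= -1e-12 && t <= 1 + 1e-12) {
          x <- a + min(max(t, 0), 1) * ab
          pts[m + 1, ] <- x
          break
        }
        idx <- idx + 1L
      }
    }
    list(short = FALSE, pts = pts,
         resid = sqrt(sum((pts[n_f, ] - P[nrow(P), ])^2)))
  }
  ## bisection on delta: too large a spacing runs off the end of the curve
  lo <- 0.5 * Ltot / nseg; hi <- 1.2 * Ltot / nseg
  best <- NULL
  for (iter in 1:200) {
    mid <- 0.5 * (lo + hi)
    m <- march(mid)
    if (m$short) hi <- mid else {
      best <- m
      if (m$resid < 1e-10 || (hi - lo) < 1e-16 * Ltot) break
      lo <- mid
    }
  }
  m <- best %||% march(lo)
  if (is.null(m) || m$short) stop("arc-length reparametrization failed")
  ## snap the final marker onto the endpoint (within bisection tolerance)
  m$pts[n_f, ] <- P[nrow(P), ]
  reference_curve(m$pts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Initial orthonormal director frame of a curve
#'
#' `D3` is the discrete unit tangent (centered differences in the
#' interior), `D1` the principal normal and `D2 = D3 x D1` the binormal.
#' Where the curvature vanishes (the straight hook) the principal normal is
#' undefined; there `D1` is filled in by parallel transport from the nearest
#' curved marker so that the frame is continuous.
#'
#' @param curve a uniform `reference_curve`
#' @return list with matrices `D1`, `D2`, `D3` (n x 3)
#' @export
initial_frame <- function(curve) {
  stopifnot(inherits(curve, "reference_curve"))
  P <- curve$points
  n <- nrow(P)
  D3 <- matrix(0, n, 3)
  D3[1, ] <- P[2, ] - P[1, ]
  D3[n, ] <- P[n, ] - P[n - 1, ]
  if (n > 2) D3[2:(n - 1), ] <- P[3:n, ] - P[1:(n - 2), ]
  D3 <- D3 / sqrt(rowSums(D3^2))
  ## curvature direction: derivative of D3, projected off D3
  D1 <- matrix(NA_real_, n, 3)
  dT <- matrix(0, n, 3)
  dT[1, ] <- D3[2, ] - D3[1, ]
  dT[n, ] <- D3[n, ] - D3[n - 1, ]
  if (n > 2) dT[2:(n - 1), ] <- D3[3:n, ] - D3[1:(n - 2), ]
  dT <- dT - D3 * rowSums(dT * D3)
  mag <- sqrt(rowSums(dT^2))
  curved <- mag > 1e-6 * max(mag, 1e-300)
  curved <- curved & mag > 1e-10
  D1[curved, ] <- dT[curved, , drop = FALSE] / mag[curved]
  if (!any(curved)) {
    ## straight rod: any frame perpendicular to the tangent
    t0 <- D3[1, ]
    a <- if (abs(t0[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    d1 <- a - t0 * sum(a * t0)
    d1 <- d1 / sqrt(sum(d1^2))
    for (j in seq_len(n)) D1[j, ] <- .transport(d1, t0, D3[j, ])
  } else {
    idx <- which(curved)
    for (j in which(!curved)) {
      src <- idx[which.min(abs(idx - j))]
      D1[j, ] <- .transport(D1[src, ], D3[src, ], D3[j, ])
    }
  }
  ## exact orthonormalization
  D1 <- D1 - D3 * rowSums(D1 * D3)
  D1 <- D1 / sqrt(rowSums(D1^2))
  D2 <- cbind(D3[, 2] * D1[, 3] - D3[, 3] * D1[, 2],
              D3[, 3] * D1[, 1] - D3[, 1] * D1[, 3],
              D3[, 1] * D1[, 2] - D3[, 2] * D1[, 1])
  list(D1 = D1, D2 = D2, D3 = D3)
}

## minimal rotation taking tangent t0 to t1, applied to v
.transport <- function(v, t0, t1) {
  cthe <- sum(t0 * t1)
  ax <- c(t0[2] * t1[3] - t0[3] * t1[2],
          t0[3] * t1[1] - t0[1] * t1[3],
          t0[1] * t1[2] - t0[2] * t1[1])
  s <- sqrt(sum(ax^2))
  if (s < 1e-14) return(v)
  ax <- ax / s
  the <- atan2(s, cthe)
  v * cos(the) + c(ax[2] * v[3] - ax[3] * v[2],
                   ax[3] * v[1] - ax[1] * v[3],
                   ax[1] * v[2] - ax[2] * v[1]) * sin(the) +
    ax * sum(ax * v) * (1 - cos(the))
}

#' Intrinsic strain and twist of the reference configuration
#'
#' Measures the discrete strain invariants of the reference rod with the
#' same staggered operators used by the constitutive law, so that the
#' reference configuration is an exact equilibrium: evaluating the internal
#' resultants with these targets returns zero.  `Omega` are the intrinsic
#' curvature/twist components, `Gamma` the intrinsic shear/stretch measures
#' (`Gamma3` is 1 up to discretization, `Gamma1`, `Gamma2` near 0).
#'
#' @param curve uniform `reference_curve`
#' @param triads frame from [initial_frame()]
#' @return list with matrices `Omega` and `Gamma` (`n-1` x 3)
#' @export
intrinsic_strain_twist <- function(curve, triads) {
  P <- curve$points
  n <- nrow(P)
  ds <- mean(curve$spacing)
  zero <- matrix(0, n - 1, 3)
  one <- matrix(1, n - 1, 3)
  res <- cpp_rod_resultants(P, triads$D1, triads$D2, triads$D3, ds,
                            one, one, zero, zero, pi)
  list(Omega = res$strain[, 1:3, drop = FALSE],
       Gamma = res$strain[, 4:6, drop = FALSE])
}

#' Build the capsule surface marker mesh
#'
#' Tiles the capsule by azimuthal rings (latitude rings on the spherical
#' caps, equally spaced rings on the cylindrical part) with approximately
#' equal spacing, plus the two pole points.  The construction is symmetric
#' about the body centre so the markers sum to zero exactly; marker 1 is the
#' motor-side pole point.
#'
#' @param spec a [body_spec()]
#' @return matrix of reference markers `Z` (n_b x 3) with attributes
#'   `spacing` (mean nearest-neighbour distance), `motor_index`, `spec`
#' @export
build_body_mesh <- function(spec) {
  stopifnot(inherits(spec, "body_spec"))
  r <- spec$body_radius
  hc <- spec$body_length / 2 - r
  area <- 2 * pi * r * (2 * hc) + 4 * pi * r^2
  count_for <- function(hb) {
    n_lat <- max(1L, round((pi / 2) * r / hb))
    n_cyl <- max(1L, round(2 * hc / hb))
    rings <- 0L
    for (i in seq_len(n_lat)) {
      th <- (i - 0.5) * (pi / 2) / (n_lat + 0.5)
      rings <- rings + max(3L, round(2 * pi * r * cos(th) / hb))
    }
    2L * rings + n_cyl_count(hb, n_cyl, r) + 2L
  }
  n_cyl_count <- function(hb, n_cyl, r) {
    n_cyl * max(3L, round(2 * pi * r / hb))
  }
  ## bisect spacing to approach the requested marker count
  lo <- sqrt(area / spec$n_b) * 0.4
  hi <- sqrt(area / spec$n_b) * 2.5
  for (it in 1:40) {
    mid <- 0.5 * (lo + hi)
    if (count_for(mid) > spec$n_b) lo <- mid else hi <- mid
  }
  hb <- if (abs(count_for(lo) - spec$n_b) < abs(count_for(hi) - spec$n_b)) lo else hi
  n_lat <- max(1L, round((pi / 2) * r / hb))
  n_cyl <- max(1L, round(2 * hc / hb))
  pts <- list()
  ## motor pole first (motor side is +z in the construction frame)
  pts[[1]] <- c(0, 0, hc + r)
  ring <- function(rho, z, m, off) {
    ang <- off + 2 * pi * (seq_len(m) - 1) / m
    cbind(rho * cos(ang), rho * sin(ang), z)
  }
  k <- 2L
  for (i in seq_len(n_lat)) {
    th <- (i - 0.5) * (pi / 2) / (n_lat + 0.5)
    m <- max(3L, round(2 * pi * r * cos(th) / hb))
    off <- (i %% 2) * pi / m
    pts[[k]] <- ring(r * cos(th), hc + r * sin(th), m, off); k <- k + 1L
    pts[[k]] <- ring(r * cos(th), -hc - r * sin(th), m, off); k <- k + 1L
  }
  mcy <- max(3L, round(2 * pi * r / hb))
  for (j in seq_len(n_cyl)) {
    z <- -hc + (j - 0.5) * (2 * hc / n_cyl)
    pts[[k]] <- ring(r, z, mcy, (j %% 2) * pi / mcy); k <- k + 1L
  }
  pts[[k]] <- c(0, 0, -hc - r)
  Z <- do.call(rbind, pts)
  ## orient so that the motor pole lies on the -pole_axis side
  u <- -spec$pole_axis
  if (max(abs(u - c(0, 0, 1))) > 1e-12) {
    R <- .rotation_between(c(0, 0, 1), u)
    Z <- Z %*% t(R)
  }
  ## symmetric construction: enforce the exact zero-sum at round-off level
  stopifnot(max(abs(colSums(Z))) < 1e-9)
  nn <- apply(as.matrix(stats::dist(Z)), 1, function(d) min(d[d > 0]))
  structure(Z, spacing = mean(nn), motor_index = 1L, spec = spec)
}

.rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
  s <- sqrt(sum(v^2)); cthe <- sum(a * b)
  if (s < 1e-14) {
    if (cthe > 0) return(diag(3))
    w <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- w - a * sum(w * a); v <- v / sqrt(sum(v^2))
    return(2 * outer(v, v) - diag(3))
  }
  vx <- rbind(c(0, -v[3], v[2]), c(v[3], 0, -v[1]), c(-v[2], v[1], 0))
  diag(3) + vx + vx %*% vx * ((1 - cthe) / s^2)
}
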