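test_that("reference flagellum follows the helix envelope", {
  spec <- helix_spec(radius = 0.35, pitch = 1.76, L_h = 0.4, L_f = 4.2, c = 2)
  # on the hook the centreline is the straight axis
  s_hook <- c(0, 0.1, 0.25, 0.4)
  cv <- build_reference_flagellum(spec, s = s_hook)
  expect_equal(cv$points, unname(cbind(0, 0, s_hook)), tolerance = 1e-14)
  # envelope value one micron past the hook: r = R (1 - exp(-c))
  cv2 <- build_reference_flagellum(spec, s = spec$L_h + 1)
  r <- sqrt(sum(cv2$points[1, 1:2]^2))
  expect_equal(r, 0.35 * (1 - exp(-2)), tolerance = 1e-12)
  # zero radius degenerates to a straight rod of the full length
  spec0 <- helix_spec(radius = 0, pitch = 1.76, L_h = 0.4, L_f = 4.2)
  cv0 <- build_reference_flagellum(spec0)
  expect_lt(max(abs(cv0$points[, 1:2])), 1e-14)
  expect_equal(sum(cv0$spacing), spec0$L_h + spec0$L_f, tolerance = 1e-10)
  # left-handedness: with increasing s the azimuth decreases
  sv <- spec$L_h + c(2.0, 2.05)
  cvh <- build_reference_flagellum(spec, s = sv)
  ang <- atan2(cvh$points[, 2], cvh$points[, 1])
  expect_lt(ang[2], ang[1])
  # invalid specs rejected
  expect_error(helix_spec(L_f = -1), "positive")
  expect_error(build_reference_flagellum(spec, s = -0.5), "outside")
})

test_that("arc-length reparametrization gives uniform spacing and preserves length", {
  spec <- helix_spec()
  cv <- build_reference_flagellum(spec)
  # fine-quadrature arc length as the independent oracle
  f <- function(s) {
    # |X0'(s)| via analytic differentiation is avoided; dense chords converge
    NULL
  }
  dense <- build_reference_flagellum(spec, s = seq(0, spec$L_h + spec$L_f,
                                                   length.out = 60001))
  arc_true <- sum(dense$spacing)
  n_f <- round(arc_true / (spec$ds / 10))
  uni <- reparametrize_by_arclength(cv, n_f)
  sp <- uni$spacing
  expect_lt(max(abs(sp - mean(sp))) / mean(sp), 1e-6)
  expect_lt(max(abs(uni$points[1, ] - cv$points[1, ])), 1e-8)
  expect_lt(max(abs(uni$points[n_f, ] - cv$points[nrow(cv$points), ])), 1e-8)
  # 10x density: polyline length matches the dense quadrature within 1e-4
  expect_lt(abs(sum(sp) - arc_true) / arc_true, 1e-4)
  # idempotence on an already uniform polyline
  again <- reparametrize_by_arclength(uni, n_f)
  expect_lt(max(abs(again$points - uni$points)), 1e-8)
  # straight segments are exactly uniform
  seg <- reference_curve(cbind(0, 0, c(0, 0.3, 0.35, 1)))
  u2 <- reparametrize_by_arclength(seg, 5)
  expect_equal(u2$spacing, rep(0.25, 4), tolerance = 1e-9)
  expect_error(reparametrize_by_arclength(
    reference_curve(matrix(0, 3, 3)), 4), "degenerate")
})

test_that("initial frame is orthonormal with tangent D3", {
  spec <- helix_spec()
  uni <- reparametrize_by_arclength(build_reference_flagellum(spec), 40)
  tri <- initial_frame(uni)
  for (M in tri) expect_equal(rowSums(M^2), rep(1, 40), tolerance = 1e-12)
  expect_lt(max(abs(rowSums(tri$D1 * tri$D2))), 1e-12)
  expect_lt(max(abs(rowSums(tri$D1 * tri$D3))), 1e-12)
  expect_lt(max(abs(rowSums(tri$D2 * tri$D3))), 1e-12)
  # interior tangents equal normalized centred differences
  P <- uni$points
  n <- nrow(P)
  cd <- P[3:n, ] - P[1:(n - 2), ]
  cd <- cd / sqrt(rowSums(cd^2))
  expect_lt(max(abs(tri$D3[2:(n - 1), ] - cd)), 1e-12)
  # far down the filament the envelope saturates: tangent pitch approaches
  # the ideal-helix value (p/2pi)/sqrt(R^2 + (p/2pi)^2)
  b <- spec$pitch / (2 * pi)
  ideal <- b / sqrt(spec$radius^2 + b^2)
  ds <- mean(uni$spacing)
  tail_idx <- which(P[, 3] > spec$L_h + 2.5)
  tail_idx <- tail_idx[tail_idx < n - 1]
  expect_lt(max(abs(tri$D3[tail_idx, 3] - ideal)), 10 * ds^2)
})

test_that("intrinsic strains reproduce helix curvature and zero the reference", {
  spec <- helix_spec()
  uni <- reparametrize_by_arclength(build_reference_flagellum(spec), 40)
  tri <- initial_frame(uni)
  intr <- intrinsic_strain_twist(uni, tri)
  # straight rod: zero intrinsic curvature and twist
  rodc <- reference_curve(cbind(0, 0, seq(0, 1, length.out = 11)))
  trir <- initial_frame(rodc)
  intr0 <- intrinsic_strain_twist(rodc, trir)
  expect_lt(max(abs(intr0$Omega)), 1e-10)
  # reference energy with the measured intrinsics is numerically zero
  ds <- mean(uni$spacing)
  mod <- elastic_moduli(39, ds, L_h = spec$L_h)
  st <- rod_state(uni$points, tri$D1, tri$D2, tri$D3, ds)
  expect_lt(rod_energy(st, mod, intr), 1e-12)
  # filament curvature approaches the ideal helix value R/(R^2+(p/2pi)^2)
  b <- spec$pitch / (2 * pi)
  kap <- spec$radius / (spec$radius^2 + b^2)
  mids <- (seq_len(39) - 0.5) * ds
  sel <- mids > spec$L_h + 2.5 & mids < sum(uni$spacing) - 2 * ds
  kap_meas <- sqrt(intr$Omega[sel, 1]^2 + intr$Omega[sel, 2]^2)
  expect_lt(max(abs(kap_meas - kap)), 10 * ds^2)
})

test_that("capsule mesh markers sum to zero and lie on the surface", {
  spec <- body_spec(body_length = 2.4, body_radius = 0.5, n_b = 80)
  Z <- build_body_mesh(spec)
  expect_lt(max(abs(colSums(Z))), 1e-12)
  # surface membership: distance to the axis segment equals the radius
  hc <- spec$body_length / 2 - spec$body_radius
  u <- -spec$pole_axis
  ax <- Z %*% u
  axc <- pmin(pmax(ax, -hc), hc)
  d <- sqrt(rowSums((Z - outer(as.numeric(axc), u))^2))
  expect_lt(max(abs(d - spec$body_radius)), 1e-9)
  # the motor marker is the pole point on the -pole_axis side
  expect_equal(as.numeric(Z[1, ]), as.numeric(u * spec$body_length / 2),
               tolerance = 1e-12)
  # quasi-uniform: nearest-neighbour spacing within a factor 2
  nn <- apply(as.matrix(dist(Z)), 1, function(dd) min(dd[dd > 0]))
  expect_lt(max(nn) / min(nn), 2)
  expect_error(body_spec(n_b = 4), "at least 6")
  expect_error(body_spec(body_length = 0.8, body_radius = 0.5), "capsule")
})
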