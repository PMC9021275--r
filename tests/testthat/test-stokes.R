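mu <- 1e-6

test_that("blob has unit mass, finite centre and r^-7 tails", {
  eps <- 0.13
  f <- function(r) 4 * pi * r^2 * blob_value(r, eps)
  expect_equal(integrate(f, 0, Inf, rel.tol = 1e-10)$value, 1,
               tolerance = 1e-8)
  expect_equal(blob_value(0, eps), 15 / (8 * pi * eps^3), tolerance = 1e-14)
  ratio <- blob_value(10 * eps, eps) / blob_value(20 * eps, eps)
  expect_equal(ratio, 2^7, tolerance = 0.02 * 2^7)
})

test_that("far fields match the singular Stokeslet and rotlet", {
  eps <- 0.01
  x0 <- c(0.2, -0.1, 0.3)
  Fv <- c(1, 2, -0.5); Tq <- c(0.3, -1, 2)
  sysF <- force_system(rbind(x0), forces = rbind(Fv), eps = eps, mu = mu)
  sysT <- force_system(rbind(x0), torques = rbind(Tq), eps = eps, mu = mu)
  dir <- c(0.6, 0.8, 0) / 1
  x <- x0 + 100 * eps * dir
  uF <- velocity_at(rbind(x), sysF)
  expect_lt(max(abs(uF - singular_stokeslet(x, x0, Fv, mu))) /
            max(abs(uF)), 1e-3)
  uT <- velocity_at(rbind(x), sysT)
  expect_lt(max(abs(uT - singular_rotlet(x, x0, Tq, mu))) / max(abs(uT)), 1e-3)
  wT <- angular_velocity_at(rbind(x), sysT)
  expect_lt(max(abs(wT - singular_rotlet_w(x, x0, Tq, mu))) / max(abs(wT)), 1e-3)
  # regularity at the source: finite and parallel to the force
  u0 <- velocity_at(rbind(x0), sysF)
  expect_true(all(is.finite(u0)))
  expect_lt(max(abs(cross3(as.numeric(u0), Fv))) / sqrt(sum(u0^2)), 1e-12)
  # w vanishes at the location of a single point force
  expect_lt(max(abs(angular_velocity_at(rbind(x0), sysF))), 1e-12)
})

test_that("field is divergence-free and w is half the curl", {
  eps <- 0.2
  set.seed(4)
  sys <- force_system(matrix(rnorm(9), 3), forces = matrix(rnorm(9), 3),
                      torques = matrix(rnorm(9), 3), eps = eps, mu = mu)
  pts <- matrix(rnorm(300), 100, 3)
  h <- 1e-5
  graddiag <- 0
  maxdiv <- 0; maxcurlerr <- 0
  for (i in seq_len(nrow(pts))) {
    x0 <- pts[i, ]
    G <- matrix(0, 3, 3)   # G[k, ] = du/dx_k
    for (k in 1:3) {
      e <- numeric(3); e[k] <- h
      G[k, ] <- (velocity_at(rbind(x0 + e), sys) -
                 velocity_at(rbind(x0 - e), sys)) / (2 * h)
    }
    graddiag <- max(graddiag, max(abs(G)))
    maxdiv <- max(maxdiv, abs(G[1, 1] + G[2, 2] + G[3, 3]))
    curl <- c(G[2, 3] - G[3, 2], G[3, 1] - G[1, 3], G[1, 2] - G[2, 1])
    w <- angular_velocity_at(rbind(x0), sys)
    maxcurlerr <- max(maxcurlerr, max(abs(w - curl / 2)) / max(abs(w)))
  }
  expect_lt(maxdiv, 1e-6 * graddiag)
  expect_lt(maxcurlerr, 1e-5)
})

test_that("linearity and Stokeslet reciprocity", {
  eps <- 0.15
  x1 <- c(0, 0, 0); x2 <- c(0.7, -0.2, 0.4)
  for (i in 1:3) for (j in 1:3) {
    ei <- numeric(3); ei[i] <- 1
    ej <- numeric(3); ej[j] <- 1
    u12 <- velocity_at(rbind(x2), force_system(rbind(x1), forces = rbind(ej),
                                               eps = eps, mu = mu))
    u21 <- velocity_at(rbind(x1), force_system(rbind(x2), forces = rbind(ei),
                                               eps = eps, mu = mu))
    expect_equal(u12[1, i], u21[1, j], tolerance = 1e-12)
  }
  # additivity over sources and homogeneity in the strengths
  set.seed(8)
  P <- matrix(rnorm(6), 2); Fm <- matrix(rnorm(6), 2); Tm <- matrix(rnorm(6), 2)
  x <- rbind(c(0.3, 0.3, -0.1))
  u_both <- velocity_at(x, force_system(P, Fm, Tm, eps = eps, mu = mu))
  u_1 <- velocity_at(x, force_system(P[1, , drop = FALSE], Fm[1, , drop = FALSE],
                                     Tm[1, , drop = FALSE], eps = eps, mu = mu))
  u_2 <- velocity_at(x, force_system(P[2, , drop = FALSE], Fm[2, , drop = FALSE],
                                     Tm[2, , drop = FALSE], eps = eps, mu = mu))
  expect_equal(u_both, u_1 + u_2, tolerance = 1e-12)
  u_s <- velocity_at(x, force_system(P, 2.5 * Fm, 2.5 * Tm, eps = eps, mu = mu))
  expect_equal(u_s, 2.5 * u_both, tolerance = 1e-12)
})

test_that("wall image system cancels the velocity on the plane", {
  eps <- 0.12
  set.seed(3)
  src <- cbind(runif(6, -0.5, 0.5), runif(6, -0.5, 0.5), runif(6, 0.4, 2))
  Fm <- matrix(rnorm(18), 6); Tm <- matrix(rnorm(18), 6) * 0.1
  sys <- force_system(src, Fm, Tm, eps = eps, mu = mu)
  g <- as.matrix(expand.grid(x = seq(-2, 2, length.out = 20),
                             y = seq(-2, 2, length.out = 20)))
  wallpts <- cbind(g, 0)
  uw <- velocity_at(wallpts, sys, wall = TRUE)
  # compare against the field magnitude near the sources ("cell surface")
  near <- sweep(src, 2, c(0, 0, 0.15), "+")
  uref <- velocity_at(near, sys, wall = TRUE)
  expect_lt(max(abs(uw)), 1e-6 * max(abs(uref)))
  # a force parallel to the wall: normal velocity vanishes on the plane
  sysp <- force_system(rbind(c(0, 0, 0.8)), forces = rbind(c(1, 0.3, 0)),
                       eps = eps, mu = mu)
  up <- velocity_at(wallpts, sysp, wall = TRUE)
  expect_lt(max(abs(up[, 3])), 1e-12 * max(abs(velocity_at(
    rbind(c(0, 0, 0.6)), sysp))))
  # far from the wall the correction vanishes
  sysh <- force_system(rbind(c(0, 0, 1e4 * eps)), forces = rbind(c(1, 2, 3)),
                       eps = eps, mu = mu)
  at <- rbind(c(0.01, 0, 1e4 * eps))
  ufree <- velocity_at(at, sysh, wall = FALSE)
  uwall <- velocity_at(at, sysh, wall = TRUE)
  expect_lt(max(abs(uwall - ufree)) / max(abs(ufree)), 1e-3)
  # sources at or below the wall are rejected
  expect_error(velocity_at(wallpts, force_system(rbind(c(0, 0, -1)),
               forces = rbind(c(1, 0, 0)), eps = eps, mu = mu), wall = TRUE),
               "above the plane")
  # wall-corrected w equals half the finite-difference curl
  x0 <- c(0.2, -0.3, 0.5)
  h <- 1e-5
  G <- matrix(0, 3, 3)
  for (k in 1:3) {
    e <- numeric(3); e[k] <- h
    G[k, ] <- (velocity_at(rbind(x0 + e), sys, wall = TRUE) -
               velocity_at(rbind(x0 - e), sys, wall = TRUE)) / (2 * h)
  }
  curl <- c(G[2, 3] - G[3, 2], G[3, 1] - G[1, 3], G[1, 2] - G[2, 1])
  wv <- wall_corrected_fields(rbind(x0), sys)$w
  expect_lt(max(abs(wv - curl / 2)) / max(abs(wv)), 1e-5)
})

test_that("assembled cell source system is momentum-consistent", {
  cfg <- tiny_config()
  st <- initial_cell_state(cfg)
  rs <- rod_state(st$X, st$D1, st$D2, st$D3, st$ds)
  den <- force_torque_densities(
    internal_resultants(rs, st$moduli, list(Omega = st$Omega, Gamma = st$Gamma)), rs)
  body <- rigid_body_state(st$Z, T = st$T, Rot = st$Rot, Xb = st$Xb, K = cfg$K)
  Fb <- penalty_forces(body)
  # reference state, no contact, no torque: all sources vanish
  sys0 <- assemble_force_system(st$X, den, st$Xb, Fb, steric = NULL,
                                ds = st$ds, eps_f = cfg$eps_f, eps_b = 0.3,
                                mu = cfg$mu)
  expect_lt(max(abs(sys0$forces)), 1e-10)
  expect_lt(max(abs(sys0$torques)), 1e-10)
  # with an artificial contact the steric pair momenta cancel exactly
  Xclose <- st$X
  Xclose[10, ] <- st$Xb[4, ] + c(0, 0, 0.5 * cfg$steric$D)
  ster <- body_flagellum_repulsion(Xclose, st$Xb, cfg$steric,
                                   s = st$sref, ds = st$ds)
  expect_gt(max(abs(ster$rod)), 0)
  rs2 <- rod_state(Xclose, st$D1, st$D2, st$D3, st$ds)
  den2 <- force_torque_densities(
    internal_resultants(rs2, st$moduli, list(Omega = st$Omega, Gamma = st$Gamma)), rs2)
  sys <- assemble_force_system(Xclose, den2, st$Xb, Fb, steric = ster,
                               ds = st$ds, eps_f = cfg$eps_f, eps_b = 0.3,
                               mu = cfg$mu)
  # steric-only part: subtract the elastic-only assembly
  sys_el <- assemble_force_system(Xclose, den2, st$Xb, Fb, steric = NULL,
                                  ds = st$ds, eps_f = cfg$eps_f, eps_b = 0.3,
                                  mu = cfg$mu)
  dster <- sys$forces - sys_el$forces
  expect_lt(max(abs(colSums(dster))), 1e-12 * max(abs(dster)))
})
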