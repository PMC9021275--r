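test_that("torque schedules are half-open and refuse extrapolation", {
  sch <- schedule_sequence(c(pull = 0.1, wrapping = 0.2, pause = 0.05,
                             push = 0.15),
                           c(-0.002, -0.004, 0, 0.002))
  expect_equal(torque_at(sch, 0.05), -0.002)
  expect_equal(torque_at(sch, 0.2), -0.004)
  expect_equal(torque_at(sch, 0.32), 0)     # inside the pause
  expect_equal(torque_at(sch, 0.4), 0.002)
  # boundaries belong to the right-hand segment (exactly representable
  # boundaries, away from cumsum rounding)
  sch2 <- motor_schedule(c(0, 0.25), c(0.25, 0.5), c(-1, 2))
  expect_equal(torque_at(sch2, 0.25), 2)
  expect_equal(torque_at(sch2, 0.5), 2)     # final right endpoint included
  expect_equal(torque_at(sch, 0.1), -0.004)
  expect_error(torque_at(sch, 0.6), "outside")
  expect_error(torque_at(sch, -0.01), "outside")
  expect_error(motor_schedule(c(0, 0.2), c(0.1, 0.3), c(1, 2)), "contiguous")
  # the pull/wrapping phases are CW (negative), push CCW (positive)
  expect_lt(torque_at(sch, 0), 0)
  expect_gt(torque_at(sch, 0.45), 0)
})

test_that("motor ghost torque and its body reaction cancel", {
  E <- c(0, 0, 1)
  g <- motor_ghost_torque(E, 0.004)
  expect_equal(g$N_ghost, c(0, 0, -0.004))
  expect_equal(sqrt(sum(g$N_ghost^2)), 0.004)
  expect_equal(g$N_ghost / sqrt(sum(g$N_ghost^2)), -E)
  g0 <- motor_ghost_torque(E, 0)
  expect_equal(g0$N_ghost, c(0, 0, 0))
  expect_equal(g0$body_torque, c(0, 0, 0))
  # action-reaction: the flagellar side receives -N_ghost through the
  # staggered stencil, the body receives +N_ghost; the pair sums to zero
  expect_equal(-g$N_ghost + g$body_torque, c(0, 0, 0), tolerance = 1e-15)
})

test_that("alignment moment restores the proximal tangent", {
  E <- c(0, 0, 1)
  expect_equal(alignment_moment(E, E, 0.3), c(0, 0, 0))
  # perpendicular misalignment has magnitude K_m
  nperp <- alignment_moment(E, c(1, 0, 0), 0.3)
  expect_equal(sqrt(sum(nperp^2)), 0.3, tolerance = 1e-14)
  # small misalignment: the moment is antiparallel to E x D3, i.e. it
  # rotates D3 toward E
  th <- 0.05
  D3 <- c(sin(th), 0, cos(th))
  nt <- alignment_moment(E, D3, 0.3)
  rotdir <- cross3(E, D3)   # rotating about +rotdir tips D3 away from E
  expect_lt(sum(nt * rotdir), 0)
  # applying the moment as a rotation brings D3 closer to E
  ax <- nt / sqrt(sum(nt^2))
  small <- 1e-3
  D3new <- D3 * cos(small) + cross3(ax, D3) * sin(small)
  expect_gt(sum(D3new * E), sum(D3 * E))
})

test_that("clamp force pair obeys the third law", {
  cf <- clamp_forces(c(1, 2, 3), c(1, 2, 3), 2)
  expect_equal(cf$on_rod, c(0, 0, 0))
  cf2 <- clamp_forces(c(1.01, 2, 3), c(1, 2, 3), 2)
  expect_equal(cf2$on_rod, c(-0.02, 0, 0), tolerance = 1e-14)
  expect_equal(cf2$on_rod + cf2$on_body, c(0, 0, 0), tolerance = 1e-15)
})

test_that("motor module is silent at equilibrium with zero torque", {
  cfg <- tiny_config(schedule = schedule_constant(0, 0.01))
  st <- initial_cell_state(cfg)
  E <- as.numeric(st$Rot %*% st$Eref)
  expect_equal(alignment_moment(E, st$D3[1, ], cfg$K_m), c(0, 0, 0),
               tolerance = 1e-12)
  Yb1 <- st$T + as.numeric(st$Rot %*% st$Z[st$motor_index, ])
  expect_equal(clamp_forces(st$X[1, ], Yb1, cfg$K_c)$on_rod, c(0, 0, 0),
               tolerance = 1e-10)
})
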