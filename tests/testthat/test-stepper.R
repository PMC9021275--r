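test_that("the attached reference state is a discrete equilibrium", {
  cfg <- tiny_config(schedule = schedule_constant(0, 0.01))
  st <- initial_cell_state(cfg)
  st2 <- step_cell(st, cfg, nsteps = 5L)
  expect_lt(max(abs(st2$X - st$X)), 1e-12)
  expect_lt(max(abs(st2$Xb - st$Xb)), 1e-12)
  expect_lt(max(abs(st2$T - st$T)), 1e-12)
  expect_lt(max(abs(st2$Rot - st$Rot)), 1e-12)
  expect_lt(max(abs(st2$D1 - st$D1)), 1e-12)
})

test_that("in the no-slip limit markers move exactly with the fluid", {
  cfg <- tiny_config(schedule = schedule_constant(0, 0.01),
                     alpha1 = Inf, alpha2 = Inf, beta = Inf)
  st <- initial_cell_state(cfg)
  # perturb a distal marker so only elastic forces act
  st$X[st$n_f - 2, ] <- st$X[st$n_f - 2, ] + c(0.01, -0.005, 0.002)
  rs <- rod_state(st$X, st$D1, st$D2, st$D3, st$ds)
  den <- force_torque_densities(
    internal_resultants(rs, st$moduli, list(Omega = st$Omega, Gamma = st$Gamma)), rs)
  body <- rigid_body_state(st$Z, T = st$T, Rot = st$Rot, Xb = st$Xb, K = cfg$K)
  sys <- assemble_force_system(st$X, den, st$Xb, penalty_forces(body),
                               ds = st$ds, eps_f = cfg$eps_f,
                               eps_b = 0.9 * st$body_spacing, mu = cfg$mu)
  u <- velocity_at(rbind(st$X, st$Xb), sys)
  st2 <- step_cell(st, cfg, nsteps = 1L)
  pred <- st$X + cfg$dt * u[seq_len(st$n_f), ]
  expect_lt(max(abs(st2$X - pred)), 1e-13)
  predb <- st$Xb + cfg$dt * u[-seq_len(st$n_f), ]
  expect_lt(max(abs(st2$Xb - predb)), 1e-13)
  # with finite drag the slip term is subtracted
  cfg2 <- tiny_config(schedule = schedule_constant(0, 0.01), alpha1 = 1e-3)
  st3 <- step_cell(st, cfg2, nsteps = 1L)
  pred3 <- st$X + cfg2$dt * (u[seq_len(st$n_f), ] - den$f / 1e-3)
  expect_lt(max(abs(st3$X - pred3)), 1e-13)
})

test_that("triads stay orthonormal over many driven steps", {
  cfg <- coarse_config(0.002, 0.004)
  traj <- run_simulation(cfg)
  st <- attr(traj, "final_state")
  err <- max(abs(rowSums(st$D1^2) - 1), abs(rowSums(st$D2^2) - 1),
             abs(rowSums(st$D3^2) - 1), abs(rowSums(st$D1 * st$D2)),
             abs(rowSums(st$D1 * st$D3)), abs(rowSums(st$D2 * st$D3)))
  expect_lt(err, 1e-9)   # 1e4 steps of the exact rotation map
  expect_true(all(diff(traj$t) > 0))
  # orientation stays a proper rotation
  expect_lt(max(abs(crossprod(st$Rot) - diag(3))), 1e-9)
})

test_that("runs are deterministic and self-describing", {
  cfg <- coarse_config(0.002, 0.002)
  t1 <- run_simulation(cfg)
  t2 <- run_simulation(cfg)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_named(as.data.frame(t1)[1:4], c("t", "Tx", "Ty", "Tz"))
  # forward speed from records agrees with the recorded instantaneous values
  vf <- forward_speed(t1)
  expect_equal(length(vf), nrow(t1))
  expect_lt(abs(mean(vf[-1]) - mean(t1$Vf[-1])) / max(abs(t1$Vf[-1])), 0.2)
})

test_that("failures carry stage and time information", {
  cfg <- coarse_config(0.002, 0.002, dt = 1e-4, auto_halve_dt = TRUE)
  expect_error(run_simulation(cfg), "blow-up|did not converge")
  st <- initial_cell_state(coarse_config(0.002, 0.001))
  st$t <- 5  # outside the schedule
  expect_error(step_cell(st, coarse_config(0.002, 0.001)), "schedule")
})
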