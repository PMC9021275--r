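test_that("steady detection accepts constants and rejects ramps", {
  tr <- make_synthetic_trajectory("constant_run",
                                  list(v = c(3, 0, 0), E = c(-1, 0, 0),
                                       duration = 0.2, dt = 1e-3))
  st <- detect_steady(tr, window = 0.02)
  expect_false(is.null(st))
  expect_lt(st$start, 0.03)
  expect_equal(st$Vf_mean, 3, tolerance = 1e-6)
  # a linear ramp has no steady segment
  ramp <- tr
  ramp$Tx <- 50 * ramp$t^2   # Vf grows linearly in t
  ramp$Vf <- forward_speed(ramp)
  expect_null(detect_steady(ramp, window = 0.02))
  expect_error(detect_steady(tr, window = 0.2), "shorter")
})

test_that("turn angle and longitude are recovered from constructed paths", {
  for (case in list(c(60, 120), c(25, 310), c(100, 45))) {
    tr <- make_synthetic_trajectory("helix_line",
                                    list(theta = case[1], phi = case[2]))
    truth <- attr(tr, "truth")
    tl <- turn_angle_longitude(tr, pre = truth$pre, post = truth$post)
    expect_lt(abs(tl["theta"] - case[1]), 1)
    dphi <- abs(tl["phi"] - case[2]) %% 360
    expect_lt(min(dphi, 360 - dphi), 1)
  }
  # collinear pre/post: theta = 0; reversed: theta = 180
  tr0 <- make_synthetic_trajectory("helix_line",
                                   list(theta = 0, phi = 0, radius = 1e-9))
  truth <- attr(tr0, "truth")
  expect_lt(turn_angle_longitude(tr0, truth$pre, truth$post)["theta"], 1)
  tr180 <- make_synthetic_trajectory("helix_line",
                                     list(theta = 180, phi = 0, radius = 1e-9))
  truth <- attr(tr180, "truth")
  expect_gt(turn_angle_longitude(tr180, truth$pre, truth$post)["theta"], 179)
  # too-short segments are an error
  expect_error(turn_angle_longitude(tr0, c(0, 1e-9), truth$post), "short")
})

test_that("straight push/pull/pause sequences only give 0 or 180 degrees", {
  # piecewise straight path: forward, pause, backward, forward
  dt <- 1e-3
  t <- seq(0, 0.4, by = dt)
  v <- ifelse(t < 0.1, 5, ifelse(t < 0.15, 0, ifelse(t < 0.3, -4, 5)))
  x <- cumsum(v) * dt
  Tm <- cbind(x, 0, 0)
  E <- matrix(rep(c(-1, 0, 0), each = length(t)), ncol = 3)
  tr <- lophoswim:::.traj_frame(t, Tm, E)
  th1 <- turn_angle_longitude(tr, pre = c(0.0, 0.1), post = c(0.16, 0.29))["theta"]
  th2 <- turn_angle_longitude(tr, pre = c(0.0, 0.1), post = c(0.31, 0.4))["theta"]
  expect_lt(abs(th1 - 180), 1)
  expect_lt(abs(th2 - 0), 1)
})

test_that("wall outcome classifier separates escape from trapping", {
  esc <- make_synthetic_trajectory("wall_escape")
  expect_equal(as.character(wall_escape(esc, h_esc = 4.8)), "escaping")
  trap <- make_synthetic_trajectory("wall_trapped")
  expect_equal(as.character(wall_escape(trap, h_esc = 4.8)), "trapped")
  # monotone but still low at the end: trapped under the height condition
  slow <- make_synthetic_trajectory("wall_escape", list(rate = 2))
  expect_equal(as.character(wall_escape(slow, h_esc = 4.8)), "trapped")
})

test_that("mode classifier follows the wrap-fraction rule on synthetic cells", {
  cfg <- tiny_config()
  st <- initial_cell_state(cfg)
  nf <- st$n_f
  dt <- 1e-3
  t <- seq(0, 0.2, by = dt)
  mk <- function(vf, tau, snap) {
    E <- matrix(rep(c(0, 0, 1), each = length(t)), ncol = 3)
    Tm <- cbind(0, 0, -vf * t)
    df <- lophoswim:::.traj_frame(t, Tm, E)
    df$phase_motor <- sign(tau) * 2 * pi * 100 * t
    cfg2 <- cfg
    cfg2$schedule <- schedule_constant(tau, max(t))
    attr(df, "config") <- cfg2
    attr(df, "snapshots") <- rep(list(snap), 5)
    attr(df, "snapshot_times") <- seq(0, max(t), length.out = 5)
    df
  }
  # extended rod ahead of the motor pole: push under CCW
  ext <- cbind(0, 0, cfg$body$body_length / 2 + st$sref)
  tr_push <- mk(vf = 10, tau = 0.002, snap = ext)
  expect_equal(as.character(classify_mode(tr_push)), "push")
  # same geometry under CW: pull
  tr_pull <- mk(vf = -8, tau = -0.002, snap = ext)
  expect_equal(as.character(classify_mode(tr_pull)), "pull")
  # rod coiled on the body surface: wrapping under CW, overwhirling under CCW
  ang <- st$sref * 2
  coil <- cbind((cfg$body$body_radius + 0.1) * cos(ang),
                (cfg$body$body_radius + 0.1) * sin(ang),
                seq(cfg$body$body_length / 2, -cfg$body$body_length / 2,
                    length.out = nf))
  tr_wrap <- mk(vf = 2, tau = -0.004, snap = coil)
  expect_equal(as.character(classify_mode(tr_wrap)), "wrapping")
  tr_over <- mk(vf = 2, tau = 0.004, snap = coil)
  expect_equal(as.character(classify_mode(tr_over)), "overwhirling")
  # without a steady segment the label is undetermined
  tr_ramp <- tr_push
  tr_ramp$Tz <- -100 * tr_ramp$t^2
  tr_ramp$Vf <- forward_speed(tr_ramp)
  expect_equal(as.character(classify_mode(tr_ramp)), "undetermined")
})
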