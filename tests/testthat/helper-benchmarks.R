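# Benchmark simulations shared across test files, run once per session and
# cached.  The reference-resolution runs use the package defaults; the
# coarse configuration is used for trend scans where many runs are needed.

.bench_cache <- new.env(parent = emptyenv())

bench <- function(name, fn) {
  if (!exists(name, envir = .bench_cache)) {
    assign(name, fn(), envir = .bench_cache)
  }
  get(name, envir = .bench_cache)
}

bench_config <- function(tau, duration, ...) {
  sim_config(schedule = schedule_constant(tau, duration),
             record_every = 2000L, snap_every = 2L, ...)
}

# coarse resolution for parameter scans (marker spacing 0.3 um)
coarse_config <- function(tau, duration, ...) {
  args <- list(helix = helix_spec(ds = 0.3),
               body = body_spec(n_b = 40),
               eps_f = 0.3, dt = 4e-7,
               schedule = schedule_constant(tau, duration),
               record_every = 1000L, snap_every = 2L)
  do.call(sim_config, modifyList(args, list(...)))
}

bench_push <- function() bench("push", function()
  run_simulation(bench_config(0.002, 0.04)))

bench_pull <- function() bench("pull", function()
  run_simulation(bench_config(-0.002, 0.04)))

bench_wrap <- function() bench("wrap", function()
  run_simulation(bench_config(-0.004, 0.09)))

# steady motor rotation rate (Hz) over the final fraction of a run
motor_rate <- function(traj, frac = 0.3) {
  n <- nrow(traj)
  i0 <- max(1, floor(n * (1 - frac)))
  (traj$phase_motor[n] - traj$phase_motor[i0]) /
    (traj$t[n] - traj$t[i0]) / (2 * pi)
}

body_rate <- function(traj, frac = 0.3) {
  n <- nrow(traj)
  i0 <- max(1, floor(n * (1 - frac)))
  (traj$roll_body[n] - traj$roll_body[i0]) / (traj$t[n] - traj$t[i0]) / (2 * pi)
}

steady_vf <- function(traj, frac = 0.3) {
  n <- nrow(traj)
  mean(traj$Vf[traj$t >= max(traj$t) - frac * (max(traj$t) - min(traj$t))])
}
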