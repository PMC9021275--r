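# Shared oracles and small builders used across the test files.

# singular (non-regularized) Stokeslet velocity, unit consistent with the
# package kernels
singular_stokeslet <- function(x, x0, F, mu) {
  r <- x - x0
  rn <- sqrt(sum(r^2))
  (F / rn + sum(F * r) * r / rn^3) / (8 * pi * mu)
}

singular_rotlet <- function(x, x0, Tq, mu) {
  r <- x - x0
  rn <- sqrt(sum(r^2))
  c(Tq[2] * r[3] - Tq[3] * r[2],
    Tq[3] * r[1] - Tq[1] * r[3],
    Tq[1] * r[2] - Tq[2] * r[1]) / (8 * pi * mu * rn^3)
}

# angular velocity of the singular rotlet: w = (1/2) curl u
singular_rotlet_w <- function(x, x0, Tq, mu) {
  r <- x - x0
  rn <- sqrt(sum(r^2))
  (-Tq / rn^3 + 3 * sum(Tq * r) * r / rn^5) / (16 * pi * mu)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# finite-difference gradient of the rod energy with respect to marker
# positions (the independent oracle for the force densities)
fd_energy_gradient <- function(state, moduli, Omega, h = 1e-7) {
  g <- matrix(0, state$n, 3)
  for (j in seq_len(state$n)) {
    for (k in 1:3) {
      Xp <- state$X; Xm <- state$X
      Xp[j, k] <- Xp[j, k] + h
      Xm[j, k] <- Xm[j, k] - h
      sp <- rod_state(Xp, state$D1, state$D2, state$D3, state$ds)
      sm <- rod_state(Xm, state$D1, state$D2, state$D3, state$ds)
      g[j, k] <- (rod_energy(sp, moduli, Omega) -
                  rod_energy(sm, moduli, Omega)) / (2 * h)
    }
  }
  g
}

# a straight rod along z with identity-like frame
straight_rod <- function(n = 12, ds = 0.1) {
  X <- cbind(0, 0, (seq_len(n) - 1) * ds)
  D3 <- matrix(rep(c(0, 0, 1), each = n), n)
  D1 <- matrix(rep(c(1, 0, 0), each = n), n)
  D2 <- matrix(rep(c(0, 1, 0), each = n), n)
  rod_state(X, D1, D2, D3, ds)
}

# smooth random perturbation of a rod state (positions only), built from a
# few low-order Fourier modes so the perturbation is resolved
perturb_rod <- function(state, amp = 1e-3, seed = 1) {
  set.seed(seed)
  n <- state$n
  s <- seq(0, 1, length.out = n)
  X <- state$X
  for (k in 1:3) {
    for (m in 1:3) {
      X[, k] <- X[, k] + amp * rnorm(1) * sin(pi * m * s + runif(1, 0, pi))
    }
  }
  rod_state(X, state$D1, state$D2, state$D3, state$ds)
}

random_rotation <- function(seed = 1) {
  set.seed(seed)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0.1, 2.5)
  vx <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]), c(-ax[2], ax[1], 0))
  diag(3) + sin(th) * vx + (1 - cos(th)) * vx %*% vx
}

# small reference cell configuration used by module-level tests (cheap)
tiny_config <- function(...) {
  args <- list(helix = helix_spec(ds = 0.3, L_f = 3.0, L_h = 0.3),
               body = body_spec(n_b = 40),
               schedule = schedule_constant(0.002, 0.01),
               dt = 5e-7, record_every = 200L, snap_every = 2L,
               auto_halve_dt = FALSE)
  do.call(sim_config, modifyList(args, list(...)))
}
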