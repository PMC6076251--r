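test_that("time step above the stability bound is rejected by name", {
  p <- chrom(eta_b = 66, eta_s = 162)
  sp <- relaxation_times(p, 2.2e5)
  expect_error(simulate_mode(p, 2.2e5, dt = sp$tau1 / 5, n_steps = 10),
               "tau_fast/10")
})

test_that("trajectories are bit-reproducible given the seed", {
  p <- chrom(eta_b = 66, eta_s = 162)
  t1 <- simulate_mode(p, 2.2e5, dt = 0.01, n_steps = 500, seed = 42)
  t2 <- simulate_mode(p, 2.2e5, dt = 0.01, n_steps = 500, seed = 42)
  t3 <- simulate_mode(p, 2.2e5, dt = 0.01, n_steps = 500, seed = 43)
  expect_identical(t1$u, t2$u)
  expect_false(identical(t1$u, t3$u))
  # the simulator must not disturb the caller's RNG stream
  set.seed(1); a <- stats::rnorm(1)
  set.seed(1); invisible(simulate_mode(p, 2.2e5, dt = 0.01, n_steps = 10,
                                       seed = 5)); b <- stats::rnorm(1)
  expect_identical(a, b)
})

test_that("zero noise decays deterministically from any initial state", {
  p <- chrom(eta_b = 66, eta_s = 162)
  traj <- simulate_mode(p, 2.2e5, noise_level = 0, dt = 0.005,
                        n_steps = 4000, seed = 1, init = c(0.1, 1))
  expect_equal(traj$u[length(traj$u)], 0, tolerance = 1e-6)
  expect_true(all(abs(traj$u[-(1:2)]) <= abs(traj$u[2]) + 1e-12))
  # drag-only variant also decays
  tr0 <- simulate_mode(chrom(), 2.2e5, noise_level = 0, dt = 1e-4,
                       n_steps = 2000, seed = 1, init = c(0, 1))
  expect_lt(abs(tr0$u[2001]), 1)
})

test_that("halving dt changes the deterministic decay rate by < 2%", {
  p <- chrom(eta_b = 66, eta_s = 162)
  rate_of <- function(dt) {
    traj <- simulate_mode(p, 2.2e5, noise_level = 0, dt = dt,
                          n_steps = round(4 / dt), seed = 1, init = c(0.1, 1))
    t <- seq_along(traj$u) * dt - dt
    sel <- t > 1.5 & t < 3.5  # late times: slow mode dominates
    -stats::coef(stats::lm(log(abs(traj$u[sel])) ~ t[sel]))[[2]]
  }
  r1 <- rate_of(0.01)
  r2 <- rate_of(0.005)
  expect_lt(abs(r1 / r2 - 1), 0.02)
  # and both near the model's slow rate
  expect_equal(r2, 1 / relaxation_times(p, 2.2e5)$tau2, tolerance = 0.02)
})

test_that("empirical autocovariance estimator behaves on known inputs", {
  p <- chrom(eta_b = 66, eta_s = 162)
  traj <- simulate_mode(p, 2.2e5, dt = 0.01, n_steps = 5000, seed = 2)
  expect_error(empirical_acf(traj, max_lag = 20), "run length / 5")
  # constant series: zero after mean removal
  traj_c <- traj; traj_c$u <- rep(3, length(traj$u))
  a <- empirical_acf(traj_c, max_lag = 1)
  expect_equal(a$acf, rep(0, nrow(a)))
  # white-noise null: |ACF(h)| < 3/sqrt(n) at positive lags
  trw <- traj
  set.seed(8)
  trw$u <- stats::rnorm(20000)
  aw <- empirical_acf(trw, max_lag = 0.1)
  expect_equal(aw$acf[1], stats::var(trw$u) * (1 - 1 / 20000),
               tolerance = 1e-6)
  expect_true(all(abs(aw$acf[-1] / aw$acf[1]) < 3 / sqrt(20000)))
})

test_that("drag-only simulation relaxes on the drag-limited timescale", {
  p <- chrom()
  q <- 2.2e5
  tau_d <- relaxation_time_drag(p, q)  # ~0.39 s here
  traj <- simulate_mode(p, q, dt = tau_d / 25, n_steps = 60000, seed = 9)
  acf_emp <- empirical_acf(traj, max_lag = 3 * tau_d)
  fit <- fit_monoexponential(acf_emp)
  expect_rel(fit$model$tau1, tau_d, 0.10)
})

test_that("stationary variance and ACF match the model prediction", {
  p <- chrom(eta_b = 66, eta_s = 162)
  q <- 2.2e5
  m <- acf_model(p, q)
  dt <- 0.01
  n <- 400000  # ~4000 s, ~4200 slow relaxation times
  traj <- simulate_mode(p, q, dt = dt, n_steps = n, seed = 17)
  burn <- round(20 * m$tau2 / dt)
  u <- traj$u[-(1:burn)]
  expect_rel(stats::var(u), m$R1 + m$R2, 0.05)
  # pointwise ACF agreement within Monte-Carlo error at short lags
  traj$u <- u
  a <- empirical_acf(traj, max_lag = 2)
  pred <- predict(m, a$lag_s)
  expect_lt(max(abs(a$acf - pred)) / (m$R1 + m$R2), 0.06)
})

test_that("simulated chromosome mode round-trips through the biexp fit", {
  # q = 2 um^-1: both components carry comparable amplitude there, so both
  # times are identifiable from a finite run (at the 7 um dominant
  # wavenumber the slow component is ~1% of the variance, below the
  # autocovariance estimator noise of any desk-scale run)
  p <- chrom(eta_b = 66, eta_s = 162)
  q <- 2e6
  sp <- relaxation_times(p, q)
  dt <- 0.012
  traj <- simulate_mode(p, q, dt = dt, n_steps = 500000, seed = 23)
  acf_emp <- empirical_acf(traj, max_lag = 6 * sp$tau2)
  fit <- fit_biexponential(acf_emp, seed = 23)
  expect_rel(fit$model$tau1, sp$tau1, 0.15)
  expect_rel(fit$model$tau2, sp$tau2, 0.15)
})

test_that("synthetic generators are exact at zero noise and seeded otherwise", {
  m <- biexp_acf(R1 = 1, tau1 = 0.2, R2 = 0.5, tau2 = 1.5)
  grid <- seq(0, 5, 0.05)
  s0 <- make_synthetic_acf(m, grid, noise_sd = 0)
  expect_equal(s0$acf, predict(m, grid))
  s1 <- make_synthetic_acf(m, grid, noise_sd = 0.01, seed = 5)
  s2 <- make_synthetic_acf(m, grid, noise_sd = 0.01, seed = 5)
  expect_identical(s1$acf, s2$acf)
  mt <- microtubule_properties()
  d0 <- make_synthetic_scaling(mt, noise_cv = 0)
  expect_equal(d0$tau_s, tau_drag_of_length(d0$length_m, pi / 2, mt))
  s <- local_slope(d0)
  expect_lt(min(s), 2.6)  # both regimes visible across 2-30 um
  expect_gt(max(s), 3.4)
  d1 <- make_synthetic_scaling(mt, noise_cv = 0.15, seed = 3)
  d2 <- make_synthetic_scaling(mt, noise_cv = 0.15, seed = 3)
  expect_identical(d1$tau_s, d2$tau_s)
})

test_that("rotational forcing variant changes statistics but not decay rates", {
  p <- chrom(eta_b = 66, eta_s = 162)
  q <- 2.2e5
  tr <- simulate_mode(p, q, dt = 0.01, n_steps = 60000, seed = 3,
                      rotational_forcing = TRUE)
  tr0 <- simulate_mode(p, q, dt = 0.01, n_steps = 60000, seed = 3)
  expect_false(identical(tr$u, tr0$u))
  expect_gt(stats::var(tr$u), stats::var(tr0$u))  # extra forcing channel
  a <- empirical_acf(tr, max_lag = 4)
  fit <- fit_biexponential(a, seed = 3)
  sp <- relaxation_times(p, q)
  # decay rates are a property of (C, K), independent of where noise
  # enters; the dominant fitted component must stay inside the system's
  # rate bracket (the minor one can be a noise-level artefact)
  tau_dom <- if (abs(fit$model$R1) >= abs(fit$model$R2)) fit$model$tau1 else
    fit$model$tau2
  expect_gt(tau_dom, sp$tau1 / 2)
  expect_lt(tau_dom, sp$tau2 * 2)
})
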