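#' Overdamped Langevin simulation of one fluctuation mode
#'
#' Euler-Maruyama integration of the per-wavenumber two-field system
#' `C zdot = -K z + f(t)`, state `z = (phi, u)` (cross-section rotation and
#' transverse displacement), with white thermal forcing on the displacement
#' component only: per step the forcing sample has variance
#' `2 noise_level / dt`, i.e. `<n(t) n(t')> = 2 noise_level delta(t - t')`.
#' The 2x2 damping matrix is inverted in closed form. The time step must
#' resolve the fast relaxation: `dt < tau_fast / 10` is enforced.
#'
#' @inheritParams overdamped_matrices
#' @param noise_level Forcing strength (free relative scale); 0 gives a
#'   deterministic decay from `init`.
#' @param dt Time step (s).
#' @param n_steps Number of steps.
#' @param seed Integer seed; trajectories are reproducible given
#'   `(seed, parameters)`.
#' @param init Initial state `c(phi, u)`, default at rest.
#' @param rotational_forcing Also force the rotation equation (exploratory
#'   variant for fluctuation-dissipation-consistent forcing of both fields;
#'   the standard model forces displacement only). Default `FALSE`.
#' @return An object of class `mode_trajectory`: list with `dt`, `q`,
#'   `seed`, and numeric vectors `u`, `phi` of length `n_steps + 1`.
#' @examples
#' props <- chromosome_properties(eta_b = 66, eta_s = 162)
#' traj <- simulate_mode(props, q = 2.2e5, dt = 0.01, n_steps = 2000, seed = 7)
#' @export
simulate_mode <- function(props, q, noise_level = 1, dt, n_steps, seed = 1L,
                          init = c(0, 0), rotational_forcing = FALSE) {
  stopifnot(inherits(props, "filament_properties"), q > 0, dt > 0,
            n_steps >= 1, length(init) == 2L, noise_level >= 0)
  sp <- relaxation_times(props, q)
  tau_fast <- sp$tau1
  if (dt >= tau_fast / 10) {
    stop(sprintf(
      "dt = %g too large: must be below tau_fast/10 = %g s for these parameters",
      dt, tau_fast / 10), call. = FALSE)
  }
  m <- overdamped_matrices(props, q)
  C <- m$C; K <- m$K
  detC <- .scalar_invariants(props, q)$detC
  if (detC == 0) {
    # singular damping (no internal friction): the rotation equation is a
    # constraint phi = -(k12/k11) u; simulate the reduced scalar mode.
    k_eff <- K[2, 2] - K[1, 2]^2 / K[1, 1]
    u <- numeric(n_steps + 1)
    u[1] <- init[2]
    decay <- 1 - dt * k_eff / props$eta
    f <- .with_seed(seed, stats::rnorm(n_steps, 0,
                                       sqrt(2 * noise_level / dt)))
    for (k in seq_len(n_steps)) {
      u[k + 1] <- decay * u[k] + dt * f[k] / props$eta
    }
    phi <- -(K[1, 2] / K[1, 1]) * u
  } else {
    # closed-form inverse of C
    i11 <- C[2, 2] / detC; i12 <- -C[1, 2] / detC; i22 <- C[1, 1] / detC
    # A = I - dt * Cinv K (2x2, constant)
    a11 <- 1 - dt * (i11 * K[1, 1] + i12 * K[1, 2])
    a12 <- -dt * (i11 * K[1, 2] + i12 * K[2, 2])
    a21 <- -dt * (i12 * K[1, 1] + i22 * K[1, 2])
    a22 <- 1 - dt * (i12 * K[1, 2] + i22 * K[2, 2])
    sd_f <- sqrt(2 * noise_level / dt)
    nf <- if (rotational_forcing) 2L * n_steps else n_steps
    f <- .with_seed(seed, stats::rnorm(nf, 0, sd_f))
    phi <- numeric(n_steps + 1); u <- numeric(n_steps + 1)
    phi[1] <- init[1]; u[1] <- init[2]
    p <- init[1]; w <- init[2]
    if (rotational_forcing) {
      f1 <- f[seq_len(n_steps)]; f2 <- f[n_steps + seq_len(n_steps)]
      for (k in seq_len(n_steps)) {
        pn <- a11 * p + a12 * w + dt * (i11 * f1[k] + i12 * f2[k])
        wn <- a21 * p + a22 * w + dt * (i12 * f1[k] + i22 * f2[k])
        p <- pn; w <- wn
        phi[k + 1] <- p; u[k + 1] <- w
      }
    } else {
      for (k in seq_len(n_steps)) {
        fk <- f[k]
        pn <- a11 * p + a12 * w + dt * i12 * fk
        wn <- a21 * p + a22 * w + dt * i22 * fk
        p <- pn; w <- wn
        phi[k + 1] <- p; u[k + 1] <- w
      }
    }
  }
  structure(list(dt = dt, q = q, seed = as.integer(seed), u = u, phi = phi),
            class = "mode_trajectory")
}

#' @export
print.mode_trajectory <- function(x, ...) {
  cat(sprintf(
    "Mode trajectory: q = %g m^-1, dt = %g s, %d samples, seed %d\n",
    x$q, x$dt, length(x$u), x$seed))
  cat(sprintf("  displacement sd = %.4g\n", stats::sd(x$u)))
  invisible(x)
}

#' Empirical autocovariance of a simulated trajectory
#'
#' Standard biased autocovariance estimator of the displacement samples
#' (mean removed, normalisation `1/n`), so the lag-0 value equals the sample
#' variance.
#'
#' @param traj A [simulate_mode()] trajectory.
#' @param max_lag Largest lag time (s); must be below a fifth of the run
#'   length for acceptable estimator variance.
#' @return An [acf_series()].
#' @export
empirical_acf <- function(traj, max_lag) {
  stopifnot(inherits(traj, "mode_trajectory"), max_lag > 0)
  total <- traj$dt * (length(traj$u) - 1)
  if (max_lag >= total / 5) {
    stop(sprintf("max_lag = %g too large: must be < run length / 5 = %g s",
                 max_lag, total / 5), call. = FALSE)
  }
  nlag <- floor(max_lag / traj$dt)
  a <- stats::acf(traj$u, lag.max = nlag, type = "covariance",
                  demean = TRUE, plot = FALSE)
  acf_series(lags = seq(0, nlag) * traj$dt, values = as.numeric(a$acf))
}

#' Synthetic noisy autocorrelation series from a model curve
#'
#' Evaluates a bi-exponential model on a lag grid and adds i.i.d. Gaussian
#' measurement noise -- the structure of experimental displacement
#' autocorrelations used for fitting tests.
#'
#' @param model A [biexp_acf()].
#' @param lag_grid Strictly increasing nonnegative lags (s).
#' @param noise_sd Standard deviation of the additive noise (variance
#'   units); 0 gives exact model samples.
#' @param seed Integer seed.
#' @return An [acf_series()].
#' @export
make_synthetic_acf <- function(model, lag_grid, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(model, "biexp_acf"), noise_sd >= 0)
  vals <- predict(model, lag_grid)
  if (noise_sd > 0) {
    vals <- vals + .with_seed(seed, stats::rnorm(length(lag_grid), 0, noise_sd))
  }
  acf_series(lag_grid, vals)
}

#' Synthetic relaxation-time-versus-length dataset
#'
#' Evaluates the drag-limited two-length-scale law on a grid of filament
#' lengths and applies multiplicative lognormal noise with a given
#' coefficient of variation -- the structure of relaxation times extracted
#' from thermal-fluctuation recordings of filaments of different lengths
#' (log-spaced over 2-30 um by default).
#'
#' @param props A [filament_properties()] ([microtubule_properties()] is the
#'   natural choice).
#' @param lengths Filament lengths (m); default 25 points log-spaced over
#'   2-30 um.
#' @param q_star Dimensionless mode wavenumber, default `pi/2`.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   noise (0 gives the exact curve).
#' @param seed Integer seed.
#' @return A [length_scaling()] dataset.
#' @export
make_synthetic_scaling <- function(props,
                                   lengths = exp(seq(log(2e-6), log(30e-6),
                                                     length.out = 25)),
                                   q_star = pi / 2, noise_cv = 0.15,
                                   seed = 1L) {
  stopifnot(all(lengths > 0), noise_cv >= 0)
  tau <- tau_drag_of_length(lengths, q_star, props)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    z <- .with_seed(seed, stats::rnorm(length(lengths), 0, sdlog))
    tau <- tau * exp(z - sdlog^2 / 2)  # unit-mean multiplicative noise
  }
  length_scaling(lengths, tau)
}
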