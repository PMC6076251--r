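#' Bi-exponential autocorrelation model
#'
#' Container for the model autocorrelation
#' `R(T) = R1 exp(-T/tau1) + R2 exp(-T/tau2)` of transverse displacement;
#' the mono-exponential model is the degenerate case `R2 = 0`. The value at
#' zero lag is `R1 + R2`.
#'
#' @param R1,R2 Amplitudes (variance units); `R2 = 0` gives a
#'   mono-exponential.
#' @param tau1,tau2 Relaxation times (s), positive. By convention
#'   `tau1 <= tau2`; inputs are reordered (with their amplitudes) if needed.
#' @return An object of class `biexp_acf`.
#' @examples
#' m <- biexp_acf(R1 = 1, tau1 = 0.2, R2 = 0.5, tau2 = 1.5)
#' predict(m, lags = c(0, 0.5, 1))
#' @export
biexp_acf <- function(R1, tau1, R2 = 0, tau2 = tau1) {
  stopifnot(is.finite(R1), is.finite(R2), is.finite(tau1), is.finite(tau2),
            tau1 > 0, tau2 > 0)
  if (tau2 < tau1) {
    tmp <- c(R1, tau1); R1 <- R2; tau1 <- tau2; R2 <- tmp[1]; tau2 <- tmp[2]
  }
  structure(list(R1 = R1, R2 = R2, tau1 = tau1, tau2 = tau2),
            class = "biexp_acf")
}

#' @export
print.biexp_acf <- function(x, ...) {
  if (x$R2 == 0) {
    cat(sprintf("Mono-exponential ACF: R = %.6g, tau = %.6g s\n",
                x$R1, x$tau1))
  } else {
    cat(sprintf("Bi-exponential ACF: R1 = %.6g (tau1 = %.6g s), R2 = %.6g (tau2 = %.6g s)\n",
                x$R1, x$tau1, x$R2, x$tau2))
  }
  invisible(x)
}

#' @param object A `biexp_acf` model.
#' @param lags Nonnegative lag times (s).
#' @param ... Unused.
#' @rdname biexp_acf
#' @export
predict.biexp_acf <- function(object, lags, ...) {
  stopifnot(is.numeric(lags), all(lags >= 0))
  object$R1 * exp(-lags / object$tau1) + object$R2 * exp(-lags / object$tau2)
}

#' Displacement power spectral density of the shear-bending model
#'
#' Two-sided spectral density of transverse displacement under white thermal
#' forcing of the displacement equation with autocorrelation
#' `<n(t) n(t')> = 2 noise_level delta(t - t')`:
#' `S_u(omega) = 2 noise_level (k11^2 + omega^2 c11^2) / |det(K + i omega C)|^2`,
#' with `|det|^2 = (detK - omega^2 detC)^2 + omega^2 Nbar^2` evaluated in
#' cancellation-free form. The model autocorrelation is
#' `(1/2pi) Int S_u exp(i omega T) d omega`.
#'
#' @inheritParams overdamped_matrices
#' @param omega Angular frequencies (rad/s), vectorised.
#' @param noise_level Forcing strength (free relative scale; default 1).
#' @return Numeric vector of spectral densities.
#' @export
displacement_psd <- function(props, q, omega, noise_level = 1) {
  s <- .scalar_invariants(props, q)
  k11 <- props$B * q^2 + props$kappa * props$S
  c11 <- props$eta_b * props$I * q^2 + props$eta_s * props$A
  2 * noise_level * (k11^2 + omega^2 * c11^2) /
    ((s$detK - omega^2 * s$detC)^2 + omega^2 * s$Nbar^2)
}

#' Model autocorrelation of transverse displacement at a wavenumber
#'
#' Closed-form amplitudes of the bi-exponential autocorrelation via partial
#' fractions of the displacement power spectrum: with decay rates
#' `lambda_i = 1/tau_i`,
#' `R_i = noise_level (k11^2 - lambda_i^2 c11^2) / (detC^2 lambda_i (lambda_j^2 - lambda_i^2))`.
#' `R1 + R2` equals the lag-zero variance `Int S_u d omega / 2pi`. With both
#' internal friction coefficients zero the spectrum is a single Lorentzian
#' and a mono-exponential model (amplitude `noise_level / (k_eff eta)`,
#' time [relaxation_time_drag()]) is returned.
#'
#' The thermal forcing acts on the displacement equation only, and
#' `noise_level` is a free relative scale (no thermal-energy calibration):
#' it rescales amplitudes, never relaxation times.
#'
#' @inheritParams displacement_psd
#' @return A [biexp_acf()] model.
#' @examples
#' acf_model(chromosome_properties(eta_b = 66, eta_s = 162), q = 2.2e5)
#' @export
acf_model <- function(props, q, noise_level = 1) {
  inv <- quadratic_invariants(props, q)
  k11 <- props$B * q^2 + props$kappa * props$S
  c11 <- props$eta_b * props$I * q^2 + props$eta_s * props$A
  if (inv$detC == 0) {
    k_eff <- inv$detK / k11
    tau <- props$eta / k_eff
    return(biexp_acf(R1 = noise_level / (k_eff * props$eta), tau1 = tau))
  }
  lam <- .decay_rates(inv$detC, inv$Nbar, inv$detK)
  if (lam[1] == lam[2]) {
    stop("degenerate spectrum: repeated relaxation rate", call. = FALSE)
  }
  amp <- function(li, lj) {
    noise_level * (k11^2 - li^2 * c11^2) / (inv$detC^2 * li * (lj^2 - li^2))
  }
  biexp_acf(R1 = amp(lam[1], lam[2]), tau1 = 1 / lam[1],
            R2 = amp(lam[2], lam[1]), tau2 = 1 / lam[2])
}
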