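#' Per-wavenumber damping and stiffness matrices of the shear-bending model
#'
#' Spatial Fourier transform of the overdamped two-field equations of motion
#' for the cross-section rotation `phi` and the transverse displacement `u`
#' turns the coupled PDE system into `C zdot + K z = f(t)` per wavenumber `q`,
#' with state `z = (phi, u)`. Both matrices are symmetric positive
#' semidefinite in this sign convention.
#'
#' @param props A [filament_properties()] object.
#' @param q Wavenumber (m^-1), positive.
#' @return A list with 2x2 matrices `C` (damping) and `K` (stiffness), state
#'   ordering (rotation, displacement).
#' @export
overdamped_matrices <- function(props, q) {
  stopifnot(inherits(props, "filament_properties"))
  if (!is.numeric(q) || length(q) != 1L || !is.finite(q) || q <= 0) {
    stop("wavenumber `q` must be a single positive number", call. = FALSE)
  }
  with(props, {
    C <- matrix(c(eta_b * I * q^2 + eta_s * A, q * eta_s * A,
                  q * eta_s * A,               eta_s * A * q^2 + eta),
                2, 2)
    K <- matrix(c(B * q^2 + kappa * S, q * kappa * S,
                  q * kappa * S,       kappa * S * q^2),
                2, 2)
    list(C = C, K = K)
  })
}

# Cancellation-free closed forms for det C, the mixed invariant
# c11 k22 + c22 k11 - 2 c12 k12, and det K. Expanding the matrix entries
# directly loses 4+ digits for chromosome-scale parameters, so these forms
# are the only route used for rate computation.
.scalar_invariants <- function(props, q) {
  with(props, {
    detC <- eta_b * eta_s * I * A * q^4 + eta * (eta_b * I * q^2 + eta_s * A)
    Nbar <- (eta_b * I * kappa * S + eta_s * A * B) * q^4 +
      eta * B * q^2 + eta * kappa * S
    detK <- B * kappa * S * q^4
    list(detC = detC, Nbar = Nbar, detK = detK)
  })
}

#' Quadratic invariants governing the two relaxation times
#'
#' The decay rates `lambda = 1/tau` of the coupled shear-bending system are
#' the roots of `detC lambda^2 - Nbar lambda + detK = 0`. Equivalently, the
#' squared rates `x = 1/tau^2` solve `M x^2 - N x + P = 0` with
#' `M = detC^2`, `N = Nbar^2 - 2 detC detK`, `P = detK^2`. All three are
#' returned in cancellation-free closed form.
#'
#' @inheritParams overdamped_matrices
#' @return A list with `M`, `N`, `P` plus the underlying `detC`, `Nbar`,
#'   `detK`.
#' @export
quadratic_invariants <- function(props, q) {
  stopifnot(inherits(props, "filament_properties"))
  if (!is.numeric(q) || length(q) != 1L || !is.finite(q) || q <= 0) {
    stop("wavenumber `q` must be a single positive number", call. = FALSE)
  }
  if (props$eta == 0 && props$eta_b == 0 && props$eta_s == 0) {
    stop("degenerate system: all dissipation coefficients are zero",
         call. = FALSE)
  }
  s <- .scalar_invariants(props, q)
  list(M = s$detC^2, N = s$Nbar^2 - 2 * s$detC * s$detK, P = s$detK^2,
       detC = s$detC, Nbar = s$Nbar, detK = s$detK)
}

# Stable decay rates from the scalar invariants (Vieta trick for the slow
# root). Returns c(lambda_fast, lambda_slow); lambda_slow == lambda_fast when
# the damping matrix is singular (single-rate branch).
.decay_rates <- function(detC, Nbar, detK) {
  if (detC == 0) {
    if (Nbar == 0) {
      stop("degenerate system: no finite relaxation rate", call. = FALSE)
    }
    lam <- detK / Nbar
    return(c(lam, lam))
  }
  disc <- Nbar^2 - 4 * detC * detK
  disc <- max(disc, 0)
  lam_fast <- (Nbar + sqrt(disc)) / (2 * detC)
  lam_slow <- detK / (detC * lam_fast)
  c(lam_fast, lam_slow)
}

#' Two-timescale relaxation spectrum at a wavenumber
#'
#' Computes the two energy relaxation times `tau1 <= tau2` of the coupled
#' shear-bending system at wavenumber `q`, via the cancellation-free
#' invariants and a Vieta recovery of the slow rate. When both internal
#' friction coefficients are zero the damping matrix is singular and a single
#' (drag-limited) relaxation time remains; it is then reported as
#' `tau1 == tau2` with `degenerate = TRUE`.
#'
#' Branch identity is reported separately from the ordering: `branch1` and
#' `branch2` label each time as `"bending-like"` or `"shear-like"` by
#' proximity (in log space) to the large-wavenumber limits `eta_b I / B` and
#' `eta_s A / (kappa S)`.
#'
#' @inheritParams overdamped_matrices
#' @return An object of class `relaxation_spectrum`: list with `q`, `tau1`,
#'   `tau2`, the quadratic invariants `M`, `N`, `P`, the branch labels and a
#'   `degenerate` flag.
#' @examples
#' props <- chromosome_properties(eta_b = 66, eta_s = 162)
#' relaxation_times(props, 2.2e5)
#' @export
relaxation_times <- function(props, q) {
  inv <- quadratic_invariants(props, q)
  lam <- .decay_rates(inv$detC, inv$Nbar, inv$detK)
  tau1 <- 1 / lam[1]
  tau2 <- 1 / lam[2]
  lim <- c(bending = props$eta_b / props$E,
           shear = props$eta_s / (props$kappa * props$G))
  label <- function(tau) {
    if (any(lim <= 0)) return(NA_character_)
    d <- abs(log(tau / lim))
    c("bending-like", "shear-like")[which.min(d)]
  }
  structure(
    list(q = q, tau1 = tau1, tau2 = tau2,
         M = inv$M, N = inv$N, P = inv$P,
         branch1 = label(tau1), branch2 = label(tau2),
         degenerate = inv$detC == 0),
    class = "relaxation_spectrum")
}

#' @export
print.relaxation_spectrum <- function(x, ...) {
  cat(sprintf("Relaxation spectrum at q = %g m^-1\n", x$q))
  if (x$degenerate) {
    cat(sprintf("  single drag-limited time tau = %.6g s\n", x$tau1))
  } else {
    cat(sprintf("  tau1 = %.6g s (%s), tau2 = %.6g s (%s)\n",
                x$tau1, x$branch1 %||% "?", x$tau2, x$branch2 %||% "?"))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Single relaxation time of the bending-only (worm-like chain) model
#'
#' The classical Euler-Bernoulli result with bending internal friction:
#' `tau = (eta + eta_b I q^4) / (B q^4)`.
#'
#' @inheritParams overdamped_matrices
#' @return Relaxation time in seconds.
#' @export
relaxation_time_eb <- function(props, q) {
  stopifnot(inherits(props, "filament_properties"), q > 0)
  with(props, (eta + eta_b * I * q^4) / (B * q^4))
}

#' Single relaxation time of the drag-only shear-bending model
#'
#' With internal friction switched off, the coupled system relaxes on a
#' single time `tau_d = (kappa S eta + B eta q^2) / (kappa S B q^4)`, which
#' is strictly decreasing in `q` and recovers `eta / (B q^4)` as `q -> 0`.
#'
#' @inheritParams overdamped_matrices
#' @return Relaxation time in seconds.
#' @export
relaxation_time_drag <- function(props, q) {
  stopifnot(inherits(props, "filament_properties"), all(q > 0))
  with(props, (kappa * S * eta + B * eta * q^2) / (kappa * S * B * q^4))
}

#' Large-wavenumber limits of the two relaxation times
#'
#' As `q -> Inf` the two times become wavenumber-independent:
#' `tau1 -> eta_b I / B = eta_b / E` (bending internal friction) and
#' `tau2 -> eta_s A / (kappa S) = eta_s / (kappa G)` (shear internal
#' friction).
#'
#' @inheritParams overdamped_matrices
#' @return Named numeric vector `c(tau1 = ..., tau2 = ...)` (seconds).
#' @export
large_q_limits <- function(props) {
  stopifnot(inherits(props, "filament_properties"))
  c(tau1 = props$eta_b / props$E,
    tau2 = props$eta_s / (props$kappa * props$G))
}

#' Small-wavenumber limits of the two relaxation times
#'
#' As `q -> 0`, `tau1 -> eta_s A / (kappa S)` while `tau2 -> eta / (B q^4)`,
#' the drag-over-bending divergence of the classical single-timescale model:
#' long-wavelength fluctuations are rigid-body-like and limited by external
#' drag, not internal friction.
#'
#' @inheritParams overdamped_matrices
#' @return Named numeric vector `c(tau1 = ..., tau2 = ...)` (seconds).
#' @export
small_q_limits <- function(props, q) {
  stopifnot(inherits(props, "filament_properties"), q > 0)
  c(tau1 = props$eta_s / (props$kappa * props$G),
    tau2 = props$eta / (props$B * q^4))
}
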