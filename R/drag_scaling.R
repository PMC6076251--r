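#' Drag-limited relaxation time as a function of filament length
#'
#' For a filament with no internal friction, writing the mode wavenumber as
#' `q = q*/L` (with `q*` the dimensionless mode wavenumber, `pi/2` for the
#' fundamental cantilever mode) turns the drag-limited relaxation time into
#' an explicit two-length-scale law:
#' `tau_d = (eta / (B q*^4)) L^4 + (eta / (kappa S q*^2)) L^2`.
#' The `L^4` term is the classical bending/drag scaling; the `L^2` term is
#' contributed by shear compliance and dominates for short filaments.
#'
#' @param L Filament length(s) (m).
#' @param q_star Dimensionless mode wavenumber (`q L`), default `pi/2`.
#' @param props A [filament_properties()].
#' @return Relaxation time(s) (s); identical to
#'   `relaxation_time_drag(props, q_star / L)`.
#' @export
tau_drag_of_length <- function(L, q_star = pi / 2, props) {
  stopifnot(inherits(props, "filament_properties"), all(L > 0), q_star > 0)
  with(props,
       eta / (B * q_star^4) * L^4 + eta / (kappa * S * q_star^2) * L^2)
}

#' Length-scaling dataset of relaxation times
#'
#' @param lengths Filament lengths (m), positive and strictly increasing.
#' @param taus Relaxation times (s), same length.
#' @return An object of class `length_scaling` (also a data.frame with
#'   columns `length_m`, `tau_s`).
#' @export
length_scaling <- function(lengths, taus) {
  stopifnot(is.numeric(lengths), is.numeric(taus),
            length(lengths) == length(taus), all(lengths > 0))
  if (any(diff(lengths) <= 0)) {
    stop("lengths must be strictly increasing", call. = FALSE)
  }
  structure(data.frame(length_m = lengths, tau_s = taus),
            class = c("length_scaling", "data.frame"))
}

#' Read / write a length-scaling dataset as delimited text
#'
#' Two-column delimited text (`length_um`, `tau_s`); lengths are in
#' micrometres in the file and converted to metres on read.
#'
#' @param path File path.
#' @return `read_length_scaling` returns a [length_scaling()];
#'   `write_length_scaling` returns `path` invisibly.
#' @export
read_length_scaling <- function(path) {
  tab <- .read_two_col(path, c("length_um", "tau_s"))
  o <- order(tab[[1]])
  length_scaling(tab[[1]][o] * 1e-6, tab[[2]][o])
}

#' @param data A [length_scaling()].
#' @rdname read_length_scaling
#' @export
write_length_scaling <- function(data, path) {
  stopifnot(inherits(data, "length_scaling"))
  utils::write.csv(data.frame(length_um = data$length_m * 1e6,
                              tau_s = data$tau_s),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Fit the two-length-scale law tau = a L^4 + b L^2
#'
#' Linear least squares in the `(L^4, L^2)` basis, or (default for
#' experimental-style data with multiplicative scatter) Levenberg-Marquardt
#' minimisation of the log-residuals `log(tau) - log(a L^4 + b L^2)` with
#' positivity enforced by a log-parameterisation, started from the linear
#' fit. Coefficient `a` maps to `eta / (B q*^4)` and `b` to
#' `eta / (kappa S q*^2)`.
#'
#' @param data A [length_scaling()] dataset (at least 4 points).
#' @param log_space Minimise log-residuals (`TRUE`, default) or raw
#'   residuals (`FALSE`).
#' @param seed Unused placeholder for interface symmetry (the fit is
#'   deterministic).
#' @return An object of class `scaling_fit`: list with `a` (s m^-4), `b`
#'   (s m^-2), standard errors `se_a`, `se_b`, `log_space`, and
#'   `crossover_m` = `sqrt(b/a)`.
#' @export
fit_scaling <- function(data, log_space = TRUE, seed = 1L) {
  stopifnot(inherits(data, "length_scaling"))
  if (nrow(data) < 4L) stop("need at least 4 points", call. = FALSE)
  L <- data$length_m; tau <- data$tau_s
  if (length(unique(L)) < 2L) stop("degenerate design: all lengths equal",
                                   call. = FALSE)
  lin <- stats::lm(tau ~ 0 + I(L^4) + I(L^2))
  co <- stats::coef(lin)
  # vcov warns on an exactly-interpolating fit; the SEs are still ~0
  se <- sqrt(diag(suppressWarnings(stats::vcov(lin))))
  a <- co[[1]]; b <- co[[2]]; se_a <- se[[1]]; se_b <- se[[2]]
  if (log_space) {
    if (any(tau <= 0)) stop("log-space fit needs positive taus", call. = FALSE)
    # positive starts even if the linear fit strayed negative
    a0 <- if (a > 0) a else stats::median(tau / L^4)
    b0 <- if (b > 0) b else stats::median(tau / L^2)
    fit <- .try_nls(lt ~ log(exp(la) * L^4 + exp(lb) * L^2),
                    data = list(L = L, lt = log(tau)),
                    start = list(la = log(a0), lb = log(b0)),
                    lower = c(la = -Inf, lb = -Inf))
    if (!is.null(fit)) {
      a <- exp(fit$coef[["la"]]); b <- exp(fit$coef[["lb"]])
      # delta-method SEs on the natural scale
      n <- length(L)
      sig2 <- fit$rss / max(n - 2, 1)
      grad <- cbind(a * L^4, b * L^2) / (a * L^4 + b * L^2)
      V <- tryCatch(sig2 * solve(crossprod(grad)), error = function(e) NULL)
      if (!is.null(V)) {
        se_a <- a * sqrt(V[1, 1]); se_b <- b * sqrt(V[2, 2])
      } else se_a <- se_b <- NA_real_
    }
  }
  structure(list(a = a, b = b, se_a = se_a, se_b = se_b,
                 log_space = log_space,
                 crossover_m = if (a > 0) sqrt(max(b, 0) / a) else Inf),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat("Length-scaling fit: tau = a L^4 + b L^2\n")
  cat(sprintf("  a = %.6g +/- %.3g s/m^4, b = %.6g +/- %.3g s/m^2 (%s residuals)\n",
              x$a, x$se_a, x$b, x$se_b,
              if (x$log_space) "log" else "raw"))
  cat(sprintf("  crossover length sqrt(b/a) = %.4g um\n",
              x$crossover_m * 1e6))
  invisible(x)
}

#' Local log-log slope of relaxation time versus length
#'
#' Centered finite differences of `log(tau)` against `log(L)` (one-sided at
#' the endpoints). For data following the two-length-scale law the slope
#' rises monotonically from 2 (short, shear/drag regime) to 4 (long,
#' bending/drag regime).
#'
#' @param data A [length_scaling()] with at least 3 points, positive taus.
#' @return Numeric vector of slopes, one per data point.
#' @export
local_slope <- function(data) {
  stopifnot(inherits(data, "length_scaling"))
  if (nrow(data) < 3L) stop("need at least 3 points", call. = FALSE)
  if (any(data$tau_s <= 0)) stop("taus must be positive", call. = FALSE)
  x <- log(data$length_m); y <- log(data$tau_s)
  n <- length(x)
  s <- numeric(n)
  s[1] <- (y[2] - y[1]) / (x[2] - x[1])
  s[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    s[i] <- (y[i + 1] - y[i - 1]) / (x[i + 1] - x[i - 1])
  }
  s
}

#' Crossover length of a two-length-scale fit
#'
#' The length at which the `a L^4` and `b L^2` contributions are equal:
#' `L_c = sqrt(b/a)`. Below `L_c` the relaxation time scales as `L^2`
#' (shear/drag), above as `L^4` (bending/drag).
#'
#' @param fit A `scaling_fit` from [fit_scaling()].
#' @return Crossover length (m); `Inf` (with a warning) when `a = 0`.
#' @export
crossover_length <- function(fit) {
  stopifnot(inherits(fit, "scaling_fit"))
  if (fit$a <= 0) {
    warning("a = 0: no finite crossover length")
    return(Inf)
  }
  sqrt(max(fit$b, 0) / fit$a)
}
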