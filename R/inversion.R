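#' Dominant wavenumber of a cantilevered filament
#'
#' Thermal fluctuations of a clamped-free filament are dominated by the
#' lowest bending mode, with wavenumber `q = pi / (2 L)`. The unrounded
#' value is used throughout (rounding `q` to two decimals shifts inverted
#' relaxation times by several percent).
#'
#' @param L Filament length (m).
#' @return Wavenumber (m^-1).
#' @examples
#' dominant_wavenumber(7e-6) * 1e-6  # 0.22 um^-1
#' @export
dominant_wavenumber <- function(L) {
  stopifnot(is.numeric(L), all(L > 0))
  pi / (2 * L)
}

.coef_estimate <- function(eta_b, eta_s, method, q, physical = TRUE,
                           diagnostics = NULL) {
  structure(list(eta_b = eta_b, eta_s = eta_s, method = method,
                 wavenumber_used = q, physical = physical,
                 diagnostics = diagnostics),
            class = "coef_estimate")
}

#' @export
print.coef_estimate <- function(x, ...) {
  cat(sprintf("Internal friction estimate (%s, q = %g m^-1)\n",
              x$method, x$wavenumber_used))
  cat(sprintf("  eta_b = %.6g, eta_s = %.6g kg/(m.s)%s\n",
              x$eta_b, x$eta_s,
              if (isTRUE(x$physical)) "" else "  [UNPHYSICAL]"))
  if (!is.null(x$diagnostics)) {
    cat("  diagnostics:",
        paste(names(x$diagnostics), "=", format(x$diagnostics, digits = 6),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Internal-friction coefficients from the large-wavenumber limit
#'
#' In the large-`q` limit the two relaxation times decouple:
#' `tau1 = eta_b I / B` and `tau2 = eta_s A / (kappa S)`, so
#' `eta_b = tau1 E` and `eta_s = tau2 kappa G`.
#'
#' @param tau1,tau2 Fast and slow fitted relaxation times (s).
#' @param props A [filament_properties()] (internal friction fields unused).
#' @return A `coef_estimate`.
#' @examples
#' invert_large_q(0.13, 0.95, chromosome_properties())
#' @export
invert_large_q <- function(tau1, tau2, props) {
  stopifnot(inherits(props, "filament_properties"), tau1 >= 0, tau2 >= 0)
  .coef_estimate(eta_b = tau1 * props$E,
                 eta_s = tau2 * props$kappa * props$G,
                 method = "large_q_limit", q = Inf)
}

#' Bending internal friction from the single-timescale (worm-like chain) fit
#'
#' Rearranges the bending-only relaxation time
#' `tau = (eta + eta_b I q^4) / (B q^4)` into
#' `eta_b = tau E - eta / (I q^4)`. A negative result (drag exceeding the
#' fitted dissipation) is returned with `physical = FALSE`.
#'
#' @param tau Fitted mono-exponential relaxation time (s).
#' @param q Wavenumber (m^-1); `Inf` gives the pure limit `tau * E`.
#' @param props A [filament_properties()].
#' @return A `coef_estimate` with `eta_s = NA`.
#' @export
invert_eb <- function(tau, q, props) {
  stopifnot(inherits(props, "filament_properties"), tau >= 0, q > 0)
  eta_b <- if (is.infinite(q)) tau * props$E else
    tau * props$E - props$eta / (props$I * q^4)
  .coef_estimate(eta_b = eta_b, eta_s = NA_real_, method = "eb", q = q,
                 physical = eta_b >= 0)
}

#' Invert the full two-timescale relation for both friction coefficients
#'
#' Solves for `(eta_b, eta_s)` such that the two relaxation times of the
#' coupled shear-bending system at wavenumber `q` equal the fitted
#' `(tau1, tau2)`. The system reduces exactly: the product of the decay
#' rates fixes `detC = detK tau1 tau2` (the stiffness determinant does not
#' involve the friction coefficients), their sum then gives one linear
#' relation between `eta_b` and `eta_s`, and substituting back into `detC`
#' leaves a single quadratic in `eta_b` -- so there are at most two
#' solutions. Each positive root is verified against the forward model and
#' polished by a damped Newton iteration in log-coefficient space; when both
#' roots are physical, the one closest (in log space) to the
#' [invert_large_q()] estimate is reported and the alternate is attached to
#' the diagnostics. On success the relative residual in tau-space is below
#' 1e-9.
#'
#' @param tau1,tau2 Target relaxation times (s), `tau1 < tau2`.
#' @param q Wavenumber (m^-1).
#' @param props A [filament_properties()] providing `E, G, r, kappa, eta`
#'   (its internal friction fields are ignored).
#' @return A `coef_estimate`; if no positive-coefficient solution exists,
#'   `physical = FALSE` with diagnostics.
#' @examples
#' invert_full(0.13, 0.95, dominant_wavenumber(7e-6), chromosome_properties())
#' @export
invert_full <- function(tau1, tau2, q, props) {
  stopifnot(inherits(props, "filament_properties"), q > 0)
  if (!(tau1 > 0 && tau2 > 0 && tau1 < tau2)) {
    return(.coef_estimate(NA_real_, NA_real_, "two_timescale", q,
                          physical = FALSE,
                          diagnostics = c(reason = "requires 0 < tau1 < tau2")))
  }
  A <- props$A; I <- props$I; B <- props$B
  kS <- props$kappa * props$S; eta <- props$eta
  detK <- B * kS * q^4
  lam1 <- 1 / tau1; lam2 <- 1 / tau2
  detC_t <- detK / (lam1 * lam2)           # from the rate product
  c0 <- (lam1 + lam2) * detC_t - eta * B * q^2 - eta * kS  # linear relation
  # es = (c0 - alpha eb) / beta; detC(eb, es) = detC_t is quadratic in eb
  alpha <- I * kS * q^4
  beta <- A * B * q^4
  qa <- -(I * A * q^4) * alpha / beta
  qb <- (I * A * q^4) * c0 / beta + eta * I * q^2 - eta * A * alpha / beta
  qc <- eta * A * c0 / beta - detC_t
  disc <- qb^2 - 4 * qa * qc
  cands <- list()
  if (disc >= 0) {
    # numerically stable quadratic roots
    sq <- sqrt(disc)
    r1 <- (-qb - sign(qb) * sq) / (2 * qa)
    r2 <- qc / (qa * r1)
    for (eb in unique(c(r1, r2))) {
      es <- (c0 - alpha * eb) / beta
      if (is.finite(eb) && is.finite(es) && eb > 0 && es > 0) {
        cands[[length(cands) + 1L]] <- c(eb, es)
      }
    }
  }
  target <- log(c(tau1, tau2))
  fres <- function(x) {
    p <- set_internal_friction(props, eta_b = exp(x[1]), eta_s = exp(x[2]))
    sp <- relaxation_times(p, q)
    log(c(sp$tau1, sp$tau2)) - target
  }
  polish <- function(pair) {
    x <- log(pair)
    fx <- fres(x)
    for (it in 1:25) {
      if (max(abs(fx)) < 1e-13) break
      J <- matrix(0, 2, 2)
      for (j in 1:2) {
        h <- 1e-7
        xp <- x; xp[j] <- xp[j] + h
        J[, j] <- (fres(xp) - fx) / h
      }
      step <- tryCatch(solve(J, fx), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) break
      lam <- 1
      repeat {
        xn <- x - lam * step
        fn <- tryCatch(fres(xn), error = function(e) rep(Inf, 2))
        if (sum(fn^2) < sum(fx^2) || lam < 1e-6) break
        lam <- lam / 2
      }
      if (!all(is.finite(fn)) || sum(fn^2) >= sum(fx^2)) break
      x <- xn; fx <- fn
    }
    list(pair = exp(x), resid = max(abs(fx)))
  }
  sols <- lapply(cands, polish)
  sols <- Filter(function(s) s$resid < 1e-9, sols)
  if (!length(sols)) {
    return(.coef_estimate(NA_real_, NA_real_, "two_timescale", q,
                          physical = FALSE,
                          diagnostics = c(reason = "no positive-coefficient solution",
                                          discriminant = disc)))
  }
  seed <- invert_large_q(tau1, tau2, props)
  dist <- vapply(sols, function(s) {
    sum(abs(log(s$pair / pmax(c(seed$eta_b, seed$eta_s), 1e-300))))
  }, numeric(1))
  best <- sols[[which.min(dist)]]
  diag <- NULL
  if (length(sols) > 1L) {
    alt <- sols[[which.max(dist)]]$pair
    diag <- c(alt_eta_b = alt[1], alt_eta_s = alt[2])
  }
  .coef_estimate(eta_b = best$pair[1], eta_s = best$pair[2],
                 method = "two_timescale", q = q, physical = TRUE,
                 diagnostics = diag)
}

#' Choose between the two orderings of a bi-exponential fit
#'
#' A bi-exponential fit yields an unordered time pair; the physical
#' assignment (which time is bending-like, which shear-like) is decided by
#' consistency: for each candidate ordering, invert via the full
#' two-timescale relation at `q` and via the large-wavenumber limit, and
#' pick the ordering whose two coefficient estimates agree best (smallest
#' maximum coefficientwise relative difference), requiring positive,
#' physical estimates.
#'
#' @param pair_a,pair_b Numeric length-2 vectors `(tau1, tau2)`; normally
#'   one is the swap of the other.
#' @param q Wavenumber (m^-1).
#' @param props A [filament_properties()].
#' @return List with `chosen` (the accepted pair), `which` (`"a"` or
#'   `"b"`), `discrepancy` (per assignment), `indistinct` flag, and the two
#'   full-inversion estimates.
#' @examples
#' disambiguate_assignment(c(0.13, 0.95), c(0.95, 0.13),
#'                         dominant_wavenumber(7e-6), chromosome_properties())
#' @export
disambiguate_assignment <- function(pair_a, pair_b, q, props) {
  stopifnot(length(pair_a) == 2L, length(pair_b) == 2L)
  if (isTRUE(all.equal(pair_a[1], pair_a[2]))) {
    return(list(chosen = pair_a, which = "a", discrepancy = c(a = 0, b = 0),
                indistinct = TRUE, estimates = NULL))
  }
  score <- function(pair) {
    full <- invert_full(pair[1], pair[2], q, props)
    lim <- invert_large_q(pair[1], pair[2], props)
    if (!isTRUE(full$physical) || full$eta_b <= 0 || full$eta_s <= 0 ||
        lim$eta_b <= 0 || lim$eta_s <= 0) {
      return(list(disc = Inf, full = full))
    }
    disc <- max(abs(full$eta_b - lim$eta_b) / lim$eta_b,
                abs(full$eta_s - lim$eta_s) / lim$eta_s)
    list(disc = disc, full = full)
  }
  sa <- score(pair_a); sb <- score(pair_b)
  if (is.infinite(sa$disc) && is.infinite(sb$disc)) {
    stop("both assignments yield unphysical coefficients; diagnostics: a = ",
         paste(format(pair_a), collapse = "/"), ", b = ",
         paste(format(pair_b), collapse = "/"), call. = FALSE)
  }
  pick_a <- sa$disc <= sb$disc
  list(chosen = if (pick_a) pair_a else pair_b,
       which = if (pick_a) "a" else "b",
       discrepancy = c(a = sa$disc, b = sb$disc),
       indistinct = FALSE,
       estimates = list(a = sa$full, b = sb$full))
}
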