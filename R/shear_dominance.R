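#' Wavelength of the n-th bending mode of a clamped-free filament
#'
#' Sinusoidal approximation to the clamped-free mode shapes: mode `n` has
#' wavenumber `q_n = (2n - 1) pi / (2 L)` and wavelength
#' `lambda_n = 1 / q_n = 2 L / ((2n - 1) pi)`, strictly decreasing in `n`.
#'
#' @param L Filament length (m).
#' @param n Mode number (integer >= 1), vectorised.
#' @return Wavelength(s) (m).
#' @export
mode_wavelength <- function(L, n) {
  stopifnot(is.numeric(L), length(L) == 1L, L > 0)
  if (any(n < 1) || any(n != round(n))) {
    stop("mode number `n` must be a positive integer", call. = FALSE)
  }
  2 * L / ((2 * n - 1) * pi)
}

#' Which fluctuation modes are dominated by shear deformation
#'
#' A mode is shear-dominated when its wavelength-to-radius ratio satisfies
#' `lambda_n / r < threshold` (threshold 10 by default). With
#' `lambda_n = 2 L / ((2n - 1) pi)` this gives, in closed form, the
#' smallest shear-dominated mode as the smallest integer `n` with
#' `2n - 1 > 2 L / (threshold r pi)`.
#'
#' @param L Filament length (m).
#' @param r Filament radius (m); 12.5 nm (the standard microtubule outer
#'   radius) by default.
#' @param threshold Wavelength-to-radius ratio below which shear dominates
#'   (default 10).
#' @return An object of class `mode_criterion`: list with `L`, `r`,
#'   `threshold`, `last_bending_mode` (largest `n` not satisfying the
#'   criterion) and `first_shear_mode` (`= last_bending_mode + 1`).
#' @examples
#' shear_dominated_modes(2e-6)   # shear dominates for n > 5
#' shear_dominated_modes(10e-6)  # shear dominates for n > 25
#' @export
shear_dominated_modes <- function(L, r = 12.5e-9, threshold = 10) {
  stopifnot(L > 0, r > 0, threshold > 0)
  # smallest n with (2n - 1) > x, i.e. n = floor((x + 1) / 2) + 1
  x <- 2 * L / (threshold * r * pi)
  first <- floor((x + 1) / 2) + 1L
  structure(list(L = L, r = r, threshold = threshold,
                 last_bending_mode = as.integer(first - 1L),
                 first_shear_mode = as.integer(first)),
            class = "mode_criterion")
}

#' @export
print.mode_criterion <- function(x, ...) {
  cat(sprintf(
    "Shear-dominance criterion (lambda_n / r < %g), L = %g um, r = %g nm\n",
    x$threshold, x$L * 1e6, x$r * 1e9))
  cat(sprintf("  shear dominates bending for modes n >= %d (n > %d)\n",
              x$first_shear_mode, x$last_bending_mode))
  invisible(x)
}
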