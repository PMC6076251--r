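#' Cross-section area and second moment of a solid circular filament
#'
#' @param r Filament radius in metres.
#' @return A list with `A` (cross-sectional area, m^2) and `I` (area second
#'   moment, m^4) for a solid circular section: `A = pi r^2`, `I = pi r^4 / 4`.
#' @examples
#' section_properties(1e-6)
#' @export
section_properties <- function(r) {
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0) {
    stop("radius `r` must be a single positive finite number", call. = FALSE)
  }
  list(A = pi * r^2, I = pi * r^4 / 4)
}

#' Material, geometric and dissipation parameters of a filament
#'
#' Bundles the parameters of the coupled shear-bending model of a thermally
#' fluctuating filament: elastic moduli, radius, shear correction factor, the
#' external (hydrodynamic) drag coefficient per unit length, and the internal
#' friction coefficients for dynamic bending and dynamic shear. Derived
#' quantities -- area `A`, second moment `I`, bending stiffness `B = E I` and
#' shear stiffness `S = G A` -- are always recomputed from the primitives.
#'
#' @param E Young's modulus (Pa).
#' @param G Shear modulus (Pa). May be omitted if `poisson_ratio` is given,
#'   in which case `G = E / (2 (1 + nu))`.
#' @param r Radius (m); the cross section is solid circular.
#' @param kappa Timoshenko shear correction factor (dimensionless, in (0, 1]).
#'   0.75 is the standard value for a circular cross section.
#' @param eta External hydrodynamic drag coefficient per unit length
#'   (kg m^-1 s^-1).
#' @param eta_b Internal friction coefficient for dynamic bending
#'   (kg m^-1 s^-1).
#' @param eta_s Internal friction coefficient for dynamic shear
#'   (kg m^-1 s^-1).
#' @param poisson_ratio Optional Poisson's ratio used to derive `G` from `E`
#'   when `G` is not supplied.
#' @return An object of class `filament_properties`: a list with the
#'   primitives `E, G, r, kappa, eta, eta_b, eta_s` and derived
#'   `A, I, B, S`.
#' @examples
#' chromosome_properties()
#' filament_properties(E = 500, r = 1e-6, poisson_ratio = 0.1, eta = 1e-3)
#' @export
filament_properties <- function(E, G = NULL, r, kappa = 0.75,
                                eta = 0, eta_b = 0, eta_s = 0,
                                poisson_ratio = NULL) {
  if (is.null(G)) {
    if (is.null(poisson_ratio)) {
      stop("supply either `G` or `poisson_ratio`", call. = FALSE)
    }
    G <- E / (2 * (1 + poisson_ratio))
  }
  chk <- function(x, nm, strict = TRUE) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      stop(sprintf("`%s` must be a single finite number", nm), call. = FALSE)
    }
    if (strict && x <= 0) stop(sprintf("`%s` must be > 0", nm), call. = FALSE)
    if (!strict && x < 0) stop(sprintf("`%s` must be >= 0", nm), call. = FALSE)
    x
  }
  E <- chk(E, "E"); G <- chk(G, "G"); r <- chk(r, "r")
  kappa <- chk(kappa, "kappa")
  if (kappa > 1) stop("`kappa` must be in (0, 1]", call. = FALSE)
  eta <- chk(eta, "eta", strict = FALSE)
  eta_b <- chk(eta_b, "eta_b", strict = FALSE)
  eta_s <- chk(eta_s, "eta_s", strict = FALSE)

  sec <- section_properties(r)
  structure(
    list(E = E, G = G, r = r, kappa = kappa,
         eta = eta, eta_b = eta_b, eta_s = eta_s,
         A = sec$A, I = sec$I, B = E * sec$I, S = G * sec$A),
    class = "filament_properties")
}

#' @export
print.filament_properties <- function(x, ...) {
  cat("Filament properties (shear-bending model)\n")
  cat(sprintf("  E = %g Pa, G = %g Pa, r = %g m, kappa = %g\n",
              x$E, x$G, x$r, x$kappa))
  cat(sprintf("  drag eta = %g, internal eta_b = %g, eta_s = %g kg/(m.s)\n",
              x$eta, x$eta_b, x$eta_s))
  cat(sprintf("  derived: A = %.6g m^2, I = %.6g m^4, B = %.6g N m^2, S = %.6g N\n",
              x$A, x$I, x$B, x$S))
  invisible(x)
}

#' Replace the internal-friction coefficients of a filament
#'
#' @param props A [filament_properties()] object.
#' @param eta_b,eta_s New internal friction coefficients (kg m^-1 s^-1).
#' @return A new `filament_properties` object.
#' @export
set_internal_friction <- function(props, eta_b = props$eta_b,
                                  eta_s = props$eta_s) {
  stopifnot(inherits(props, "filament_properties"))
  filament_properties(E = props$E, G = props$G, r = props$r,
                      kappa = props$kappa, eta = props$eta,
                      eta_b = eta_b, eta_s = eta_s)
}

#' Reference parameter set: mitotic chromosome arm
#'
#' Micron-radius chromosomal filament with the elastic and drag parameters
#' used throughout the worked examples: `E` = 500 Pa, `G` = 227 Pa (Poisson
#' ratio 0.1), `r` = 1 um, `eta` = 1e-3 kg/(m.s).
#'
#' @param eta_b,eta_s Internal friction coefficients (kg m^-1 s^-1), zero by
#'   default so drag-only analyses work out of the box.
#' @return A `filament_properties` object.
#' @export
chromosome_properties <- function(eta_b = 0, eta_s = 0) {
  filament_properties(E = 500, G = 227, r = 1e-6, kappa = 0.75,
                      eta = 1e-3, eta_b = eta_b, eta_s = eta_s)
}

#' Reference parameter set: microtubule
#'
#' A stiff, strongly anisotropic filament: large longitudinal Young's modulus
#' but a soft inter-protofilament shear modulus, which places the
#' bending-to-shear crossover of the drag-limited relaxation time near 10 um
#' for the fundamental cantilever mode.
#'
#' @param eta_b,eta_s Internal friction coefficients (kg m^-1 s^-1).
#' @return A `filament_properties` object with `E` = 1.2 GPa, `G` = 1.5 kPa,
#'   `r` = 12.5 nm, `eta` = 2e-3 kg/(m.s).
#' @export
microtubule_properties <- function(eta_b = 0, eta_s = 0) {
  filament_properties(E = 1.2e9, G = 1.5e3, r = 12.5e-9, kappa = 0.75,
                      eta = 2e-3, eta_b = eta_b, eta_s = eta_s)
}

#' Read filament properties from a YAML or JSON config file
#'
#' Accepted keys: `E_Pa`, `G_Pa` (or `poisson_ratio`), `r_um`, `kappa`,
#' `eta`, `eta_b`, `eta_s`. The radius is given in micrometres at this
#' boundary and converted to metres internally; all other quantities are SI.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [filament_properties()] object.
#' @export
read_filament_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  need <- function(k) {
    if (is.null(cfg[[k]])) stop("config key missing: ", k, call. = FALSE)
    as.numeric(cfg[[k]])
  }
  opt <- function(k, default = NULL) {
    if (is.null(cfg[[k]])) default else as.numeric(cfg[[k]])
  }
  filament_properties(
    E = need("E_Pa"),
    G = opt("G_Pa"),
    r = need("r_um") * 1e-6,
    kappa = opt("kappa", 0.75),
    eta = opt("eta", 0),
    eta_b = opt("eta_b", 0),
    eta_s = opt("eta_s", 0),
    poisson_ratio = opt("poisson_ratio"))
}
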