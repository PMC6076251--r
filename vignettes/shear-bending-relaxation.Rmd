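---
title: "Two-timescale relaxation of fluctuating biofilaments: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-timescale relaxation of fluctuating biofilaments: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(timoflex)
```

## The model

A semiflexible biofilament (a chromosome arm, a microtubule) fluctuating in
a viscous medium dissipates energy through three channels: hydrodynamic drag
on its transverse motion, internal friction generated by the rate of bending
deformation, and — the distinguishing ingredient here — internal friction
generated by the rate of *shear* deformation. Classical worm-like-chain
analyses use Euler–Bernoulli kinematics, in which cross sections stay
perpendicular to the centerline; that approximation degrades for short
filaments ($L/2r < 10$) and for short-wavelength modes ($\lambda/r < 10$).
`timoflex` instead uses Timoshenko kinematics: the section rotates by a
bending angle $\varphi$ plus a shear angle, with total slope
$\partial u/\partial x = \varphi + \gamma$.

In the overdamped (inertia-free) limit, each spatial Fourier mode of
wavenumber $q$ obeys a two-field Langevin system in the state
$z = (\varphi, u)$:

$$\mathbf{C}\,\dot z + \mathbf{K}\, z = f(t),$$

with symmetric positive-semidefinite damping and stiffness matrices

$$\mathbf{C} = \begin{pmatrix} \eta_b' I q^2 + \eta_s' A & q\,\eta_s' A \\
q\,\eta_s' A & \eta_s' A q^2 + \eta \end{pmatrix}, \qquad
\mathbf{K} = \begin{pmatrix} B q^2 + \kappa S & q\,\kappa S \\
q\,\kappa S & \kappa S q^2 \end{pmatrix}.$$

Here $B = EI$ is the bending stiffness, $S = GA$ the shear stiffness,
$\kappa$ the shear correction factor (0.75 for a solid circular section),
$\eta$ the drag per unit length, and $\eta_b'$, $\eta_s'$ the internal
friction coefficients for bending and shear rates, all SI. White thermal
forcing acts on the displacement equation only.

The decay rates $\lambda = 1/\tau$ are the generalized eigenvalues of
$(\mathbf{K}, \mathbf{C})$, i.e. the roots of
$\det\mathbf{C}\,\lambda^2 - \bar N \lambda + \det\mathbf{K} = 0$ with
$\bar N = c_{11}k_{22} + c_{22}k_{11} - 2 c_{12}k_{12}$. The displacement
autocorrelation is therefore a sum of two exponentials,
$\mathcal R(T) = R_1 e^{-T/\tau_1} + R_2 e^{-T/\tau_2}$ with
$\tau_1 \le \tau_2$, against the single timescale of the bending-only
theory, $\tau = (\eta + \eta_b' I q^4)/(Bq^4)$.

### Numerical formulation

Evaluated entrywise, $\det\mathbf{C}$, $\bar N$ and $\det\mathbf{K}$ cancel
catastrophically for realistic parameters (for the chromosome values below,
$\det\mathbf{C}$ loses more than two decades against its largest product;
other regimes lose far more). `relaxation_times()` therefore uses the
expanded, cancellation-free forms

$$\det\mathbf{C} = \eta_b'\eta_s' I A q^4 + \eta(\eta_b' I q^2 + \eta_s' A),
\quad
\bar N = (\eta_b' I \kappa S + \eta_s' A B)q^4 + \eta B q^2 + \eta\kappa S,
\quad
\det\mathbf{K} = B \kappa S q^4,$$

computes the fast rate from the quadratic formula's additive branch and
recovers the slow rate from the product (Vieta), never by the subtractive
branch. The quadratic invariants reported alongside a spectrum are
$M = (\det\mathbf{C})^2$, $N = \bar N^2 - 2\det\mathbf{C}\det\mathbf{K}$,
$P = (\det\mathbf{K})^2$, whose roots in $x = 1/\tau^2$ are the squared
rates; any common positive factor in $(M, N, P)$ cancels in the times, so
only the roots are contractually meaningful. The test suite verifies the
closed forms against brute-force determinant expansions (at the scale of
the expansion terms) and against LAPACK generalized eigenvalues on a
conditioning-restricted random ensemble.

### Limits and branch identity

As $q \to \infty$ the times decouple into material ratios
$\tau_1 \to \eta_b' I/B = \eta_b'/E$ (bending) and
$\tau_2 \to \eta_s' A/\kappa S = \eta_s'/\kappa G$ (shear); as $q \to 0$,
$\tau_1 \to \eta_s'/\kappa G$ while $\tau_2 \to \eta/(Bq^4)$ diverges with
drag. Note the shear-like branch migrates between $\tau_1$ and $\tau_2$: the
package reports spectra ordered ($\tau_1 \le \tau_2$) and labels branch
identity separately, by log-space proximity to the two limits. The
wavenumber beyond which the plateaus hold to a given accuracy depends on the
friction coefficients themselves — for the fitted chromosome coefficients
the bending plateau holds to 5% only for $q \gtrsim 0.14\,\mu m^{-1}$, which
still comfortably contains the dominant mode of a 7 µm cantilever
($q_{dom} = \pi/2L \approx 0.22\,\mu m^{-1}$).

## Fitting measured autocorrelations

`fit_monoexponential()` and `fit_biexponential()` perform bounded
Levenberg–Marquardt least squares (`minpack.lm`). Two-exponential fitting is
notoriously ill-conditioned when $\tau_2/\tau_1 \lesssim 3$, so the
bi-exponential fit multi-starts from log-spaced time pairs bracketing the
lag span, a start derived from the mono fit, an optional user start, and
seeded jittered restarts (12 starts in total). Amplitudes are unconstrained
in sign — the residue formula can legitimately produce a negative term — and
positivity is checked downstream rather than imposed. The mono solution is
always among the candidates, so the bi-exponential residual sum of squares
never exceeds the mono one. Fits are unweighted by default (whether
experimental ACF fits weight the growing variance at long lags is rarely
reported); `acf_series()` accepts optional weights. Non-convergence is
flagged, never thrown. The reported misfit is a literal root mean square,
$\sqrt{\int (data - model)^2\,dT / (T_{max}-T_{min})}$ by trapezoid rule,
with the raw integral variant attached as an attribute; misfits of published
fits to unavailable experimental curves are not reproducible and are not
targeted.

## From times to friction coefficients

Given fitted $(\tau_1, \tau_2)$ at wavenumber $q$ the inverse problem for
$(\eta_b', \eta_s')$ reduces exactly: the rate product fixes
$\det\mathbf{C} = \tau_1\tau_2 \det\mathbf{K}$ (the stiffness determinant
contains no friction), the rate sum then yields a linear relation between
the two coefficients, and back-substitution leaves one quadratic — at most
two solutions, each verified forward and polished by a damped Newton
iteration in log-coefficient space (positivity by construction). When both
roots are physical the one nearest the large-$q$ estimate
($\eta_b' = \tau_1 E$, $\eta_s' = \tau_2 \kappa G$) is primary and the
alternate is attached as a diagnostic. `dominant_wavenumber()` uses the
unrounded $\pi/2L$; rounding $q_{dom}$ to two decimals (as printed tables
do) shifts inverted times by several percent.

A bi-exponential fit does not order its two components; the physical
assignment is chosen by `disambiguate_assignment()`: for each ordering,
invert via the full relation and via the large-$q$ limit and accept the
ordering whose two estimates agree best (maximum coefficientwise relative
difference), requiring positivity. The swapped ordering ($\tau_1 > \tau_2$)
is infeasible under the full relation, which is exactly why it is rejected.

## Drag-limited length scaling

With internal friction off, a single relaxation time survives,
$\tau_d = (\kappa S \eta + B\eta q^2)/(\kappa S B q^4)$. Writing $q = q^*/L$
for a mode of dimensionless wavenumber $q^*$ (fundamental cantilever mode
$q^* = \pi/2$, the default) gives the two-length-scale law

$$\tau_d = \frac{\eta}{Bq^{*4}}L^4 + \frac{\eta}{\kappa S q^{*2}}L^2,$$

whose log–log slope rises monotonically from 2 (short, shear-compliant) to
4 (long, bending/drag) through the crossover $L_c = \sqrt{b/a} =
q^*\sqrt{B/\kappa S}$. `fit_scaling()` fits $aL^4 + bL^2$ linearly in the
$(L^4, L^2)$ basis or, by default for experimental-style data whose scatter
is multiplicative on log–log axes, by Levenberg–Marquardt on log-residuals
with log-parameterised (hence positive) coefficients, seeded from the
linear fit; standard errors on the natural scale come from the delta
method. Input relaxation times are treated as ACF-decay-equivalent;
mean-squared-displacement conventions differing by a fixed factor rescale
both coefficients and leave the crossover length and slopes untouched.

## Per-mode shear dominance

Clamped-free mode $n$ is approximated as sinusoidal with wavenumber
$q_n = (2n-1)\pi/2L$, wavelength $\lambda_n = 2L/((2n-1)\pi)$. Shear
dominates bending when $\lambda_n/r < 10$; the smallest such mode has
closed form: the least integer $n$ with $2n - 1 > 2L/(10\,r\pi)$. With the
standard microtubule outer radius $r = 12.5$ nm this gives first
shear-dominated modes 6, 26 and 77 for $L = 2, 10, 30\ \mu m$ — i.e.
shear dominates for $n > 5$, $n > 25$, $n \ge 77$. (Reference tabulations
print the 30 µm entry as "$n > 77$", an off-by-one against their own
closed form's $n \ge 77$; the package reports the closed form.)

## Synthetic data

No public repository holds the underlying measurements, so the generators
are first-class:

* `simulate_mode()` integrates the per-mode system by Euler–Maruyama with
  the closed-form $2\times 2$ inverse of $\mathbf{C}$, white forcing on the
  displacement component of per-step variance $2\,\sigma^2/\Delta t$
  (`noise_level` $\sigma^2$, the Langevin convention
  $\langle n(t)n(t')\rangle = 2\sigma^2\delta$), and an enforced step bound
  $\Delta t < \tau_{fast}/10$. With no internal friction the damping matrix
  is singular; the rotation equation becomes a constraint and the reduced
  scalar mode is simulated. Higher-order integrators buy little here: the
  step bound already pins the deterministic bias to ~2% and rates differ by
  less than an order of magnitude in the regimes of interest. An optional
  `rotational_forcing` flag also forces the rotation equation, for
  exploring fluctuation–dissipation-consistent variants beyond the standard
  displacement-only model.
* `make_synthetic_acf()` emulates measured displacement autocorrelations:
  model curve plus i.i.d. Gaussian noise on a lag grid (fixtures in this
  package use 300 lags over five slow relaxation times, ~1% noise).
* `make_synthetic_scaling()` emulates relaxation-time-versus-length
  datasets: the two-length-scale law on 25 lengths log-spaced over
  2–30 µm with unit-mean lognormal noise (default coefficient of variation
  0.15, matching the visual scatter of published log–log data).

Thermal energy never enters: `noise_level` is a free relative scale that
moves amplitudes only, mirroring analyses that fit $R_1, R_2$ freely.

### What the generators do and do not emulate

The ACF generator reproduces additive measurement noise but not the
lag-correlated error of an autocovariance estimated from one finite
trajectory; the simulator covers that case. Neither adds drift,
photobleaching-like trends, nor tracking outliers. The scaling generator
draws independent lengths, whereas real filament sets share calibration
errors. Passing tests therefore demonstrate correct model structure and
estimator behaviour under the stated noise models, not robustness to every
experimental artefact.

One finding matters when designing round-trip experiments: under
displacement-only white forcing, the slow (shear-like) component at the
dominant wavenumber of a 7 µm chromosome carries only ~1% of the
displacement variance (the amplitude ratio is independent of the noise
normalisation). Its time is then unrecoverable at percent-level noise — and
published two-component fits of experimental data at such wavenumbers imply
amplitude structure richer than this forcing model produces. Round-trip
validations here use $q = 2\ \mu m^{-1}$, where the two components carry
comparable weight and the times sit on their large-$q$ plateaus.

## Reference parameter sets and defaults

* `chromosome_properties()`: $E = 500$ Pa, $G = 227$ Pa (Poisson ratio
  0.1), $r = 1\ \mu m$, $\eta = 10^{-3}$ kg/(m·s) — the estimated
  properties of cantilevered mitotic chromosome arms.
* `microtubule_properties()`: $E = 1.2$ GPa, $G = 1.5$ kPa,
  $r = 12.5$ nm, $\eta = 2\times 10^{-3}$ kg/(m·s). Published
  length-scaling analyses print no material constants, so these are chosen
  once from the microtubule literature: a GPa-scale longitudinal modulus,
  a kPa-scale inter-protofilament shear modulus (the lattice is strongly
  anisotropic), the standard outer radius, and a slender-body drag
  estimate. They place the crossover length at
  $L_c = (\pi/2)\sqrt{B/\kappa S} \approx 10\ \mu m$, the value the
  length-scaling experiments exhibit, and give millisecond-to-second
  relaxation times over 2–30 µm.
* $\kappa$ defaults to 0.75; $q^*$ defaults to $\pi/2$; thresholds and
  seeds are explicit arguments everywhere, with deterministic defaults.

## Problem sizes used in validation

The test suite runs the eigenvalue cross-check on 1000 restricted random
draws; fitting ensembles use 100 synthetic ACFs and 50 scaling datasets;
Langevin round trips use $4$–$5\times 10^5$ steps ($\Delta t$ about a tenth
of the step bound, runs of several thousand slow relaxation times). These
sizes put Monte-Carlo error comfortably inside the asserted tolerances
(e.g. autocovariance noise a few percent of the slow amplitude at
$q = 2\ \mu m^{-1}$).

## Known limitations

* Hydrodynamics is a scalar per-length drag; no anisotropic or nonlocal
  interaction tensors, and no rotational drag on $\varphi$.
* Mode shapes are sinusoidal approximations to clamped-free
  eigenfunctions; no exact cantilever eigenfunction computation.
* Repeated relaxation rates (exactly critical spectra) are reported as an
  error by `acf_model()` rather than handled by a confluent limit.
* No uncertainty propagation from fit covariance to inverted coefficients.
* Inertial (wave-propagation) dynamics are out of scope by construction.
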