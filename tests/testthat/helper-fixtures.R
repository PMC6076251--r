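# Shared fixtures and independent oracles.

# Chromosome-arm parameters used across the worked examples.
chrom <- function(eta_b = 0, eta_s = 0) chromosome_properties(eta_b, eta_s)

# Independent relaxation-time oracle: generalized eigenvalues of (K, C)
# via LAPACK on the explicitly assembled matrices (naive route -- exactly
# what the closed forms are guarding against at extreme parameters, but
# accurate in well-conditioned regimes).
eigen_taus <- function(props, q) {
  m <- overdamped_matrices(props, q)
  # diagonal equilibration: a congruence by D leaves the generalized
  # eigenvalues of (K, C) unchanged but fixes the raw scale disparity
  # between the rotation and displacement states
  D <- diag(1 / sqrt(diag(m$C)))
  lam <- eigen(solve(D %*% m$C %*% D, D %*% m$K %*% D),
               only.values = TRUE)$values
  sort(1 / Re(lam))
}

# Log-uniform random filament draws over physically sensible ranges.
random_props <- function() {
  E <- 10^stats::runif(1, 1, 9)
  filament_properties(
    E = E,
    G = E * 10^stats::runif(1, -4, 0),
    r = 10^stats::runif(1, -8, -5),
    kappa = stats::runif(1, 0.5, 1),
    eta = 10^stats::runif(1, -5, -2),
    eta_b = 10^stats::runif(1, -1, 3),
    eta_s = 10^stats::runif(1, -1, 3))
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(max(abs(actual / expected - 1)), tol)
}

# Draws restricted to parameter sets where the naive matrix route itself is
# numerically trustworthy: limited cancellation in det C and a rate ratio
# the nonsymmetric eigensolver can resolve at the comparison tolerance.
random_props_conditioned <- function() {
  repeat {
    p <- random_props()
    q <- 10^stats::runif(1, 2, 7)
    m <- overdamped_matrices(p, q)
    cancel <- det(m$C) / (m$C[1, 1] * m$C[2, 2] + m$C[1, 2]^2)
    if (cancel <= 1e-4) next
    sp <- relaxation_times(p, q)
    # LAPACK's error on the slow rate grows like eps * ratio / cancel
    if (sp$tau2 / sp$tau1 / cancel < 3e4) return(list(props = p, q = q))
  }
}
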