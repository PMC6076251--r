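Package: timoflex
Title: Shear-Bending Relaxation Dynamics of Thermally Fluctuating Biofilaments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Models the thermal fluctuations of semiflexible biofilaments
    (chromosomes, microtubules) with a Timoshenko beam that dissipates energy
    through dynamic bending, dynamic shear and hydrodynamic drag. Provides
    closed-form two-timescale relaxation spectra per wavenumber, bi-exponential
    autocorrelation models and their nonlinear least-squares fitting, inversion
    of fitted relaxation times into internal-friction coefficients, drag-limited
    L^4 + L^2 length-scaling analysis, a per-mode shear-dominance criterion, and
    an overdamped Langevin simulator for generating synthetic datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
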