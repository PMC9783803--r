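Package: hbdyn
Title: Hydrogen-Bond Dynamics from Molecular-Dynamics and Path-Integral Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of proton dynamics in D-H...A hydrogen bridges from
    molecular-dynamics trajectories: vibrational power spectra from the
    Fourier transform of the atomic velocity autocorrelation function,
    two-dimensional proton-position histograms, potentials of mean force by
    Boltzmann inversion, proton-transfer detection with hysteresis, and
    bookkeeping of static bond descriptors (QTAIM bond-critical-point
    properties with Espinosa bond energies, and SAPT interaction-energy
    components). Includes a synthetic trajectory generator: classical
    velocity-Verlet molecular dynamics and staging path-integral molecular
    dynamics with Nose-Hoover chain thermostats on analytic proton-transfer
    potentials, plus exact finite-difference quantum references, so every
    analysis stage can be validated at desk scale. Reads and writes
    multi-frame XYZ and CPMD-style TRAJECTORY files and handles triclinic
    minimum-image geometry.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
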