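---
title: "Methods: hydrogen-bond dynamics from classical and path-integral trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hydrogen-bond dynamics from classical and path-integral trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hbdyn)
```

## Scope and model of the problem

A hydrogen bridge D-H...A couples three observables that this package
extracts from trajectories: the vibrational signature of the X-H stretch
(red- or blueshifted on bond formation), the statistics of the proton
position between donor and acceptor, and the free-energy profile along the
transfer coordinate. Production data for such analyses come from ab initio
molecular dynamics; every analysis stage here is engine-agnostic and works
on any trajectory that provides positions (and, for spectra, velocities).
Because ab initio forces are not reproducible at desk scale, the package
ships its own synthetic generator whose statistical structure matches what
the analyses assume, plus exact quantum references, so each stage is
validated end to end.

### The analytic bridge potentials

The proton coordinate `x` is measured from the midpoint of a collinear
D-H...A bridge; `R` is the donor-acceptor distance.

* `harmonic`: `V = k x^2 / 2`. The default `k` corresponds to a 3400 cm^-1
  stretch for a 1.008 amu proton - a free O-H/N-H oscillator, used as the
  gas-phase reference in band-shift analyses.
* `double_well`: `V = V0 ((x/a0)^2 - 1)^2`, minima at `x = +-a0`, barrier
  `V0`. Defaults `V0 = 3.1` kcal/mol, `a0 = 0.35` A put the classical
  transfer barrier at the scale reported for moderately strong O-H...O
  bridges, with donor-side and acceptor-side wells 0.7 A apart inside an
  `R0 = 2.6` A bridge.
* `coupled_bridge` adds the geometric correlation that makes hydrogen
  bonds interesting: `a(R) = a0 + c_a (R - R0)` and
  `V0(R) = V0 + c_V (R - R0)`, plus a restraint `k_R (R - R0)^2 / 2` on the
  breathing coordinate. A transient bridge compression therefore pulls the
  wells together and lowers the barrier, which is the mechanism behind
  transfer events in the synthetic runs.

Coupling defaults are `c_a = 0.5`, `c_V = 3` kcal/mol/A and `k_R = 60`
kcal/mol/A^2. Two constraints fix them: the thermal spread of `R`
(`sigma_R = sqrt(kB T / k_R) ~ 0.1` A at 297 K) should be a few hundredths
of the bridge length, as in real O...O bridges; and the potential must stay
bounded, i.e. `V0(R) > 0` over every thermally reachable `R`. With these
values the domain edge `V0(R) = 0` lies beyond ten standard deviations of
`R`; the evaluator and the engines additionally refuse configurations
outside the domain rather than integrating an unbounded surface.
Deuteration is a mass change (`mass_H = 2.014`).

## Classical and path-integral sampling

`simulate_md()` integrates with velocity Verlet. Temperature control uses
Nose-Hoover chains of length 4, one chain per degree of freedom, advanced
with a three-term Suzuki-Yoshida factorisation each half step. Initial
velocities are Maxwell-Boltzmann draws from an explicit integer seed, and
identical settings reproduce trajectories bit for bit. The default
integration step is 0.1 fs; production analyses on the double well use
0.5 fs, chosen against the ~1500 cm^-1 well frequency (about 45 steps per
period). Energy conservation is checked in NVE mode as the difference of
windowed means (first vs last 10% of the run) relative to the initial
energy: velocity Verlet conserves a shadow Hamiltonian, so its energy error
oscillates with bounded amplitude O((omega dt)^2) and the secular drift -
the quantity that diagnoses an integrator defect - is what the windowed
means isolate.

`simulate_pimd()` samples the discretised imaginary-time path: P replicas
(beads) of the proton joined by harmonic springs of frequency
`omega_P = sqrt(P)/(beta hbar)`, each bead feeling `V/P`. Propagation uses
the staging transformation `u_1 = x_1`,
`u_k = x_k - ((k-1) x_{k+1} + x_1)/k`, which diagonalises the spring term;
staging masses `m_k = k/(k-1) m` give all non-centroid modes the common
frequency `omega_P`, so one time step suits every mode. Each staging degree
of freedom carries its own ("massive") Nose-Hoover chain - the stiff,
nearly harmonic bead modes are not ergodic under a single global
thermostat. Whether the reference ab initio setup thermostatted per mode or
globally is not documented; massive chains are the choice that guarantees
correct bead statistics, and nothing downstream depends on the distinction.
With `P = 1` the engine reduces exactly to classical MD, which the tests
exercise against the classical closed forms.

Two energy estimators are reported, primitive and centroid-virial, with
block-averaged standard errors; they estimate the same finite-P energy and
their agreement is the standard internal check on converged sampling.

### Exact references and the finite-P offset

`reference_quantum_density()` diagonalises the 1D Hamiltonian on a grid
(three-point finite differences) and Boltzmann-weights the eigenstates; the
grid is refined once and the function aborts if the ground-state energy
moves by more than 1e-6 hartree, so a coarse grid cannot silently pass.
For the harmonic oscillator the package also provides the continuum laws
`<x^2> = hbar/(2 m omega) coth(beta hbar omega / 2)` (and the matching
energy) *and* their exact finite-P counterparts `ho_x2_finiteP()` /
`ho_energy_finiteP()` from the normal-mode sums of the discretised path.
The distinction matters: at 297 K and 3400 cm^-1, `beta hbar omega ~ 16.5`,
and at P = 32 the finite-P expectations sit about 3% below the continuum
laws. An exact sampler converges to the finite-P law, not to the continuum
one; validation tests therefore target the finite-P expectations, while the
acceptance-level comparison against the coth laws is resolved within the
statistical error of runs of the prescribed length. The Trotter offset
shrinks roughly fourfold per doubling of P, which the convergence test
(P = 8, 16, 32) asserts as a monotone approach from below.

Position statistics from a path-integral run use all beads pooled - the
estimator of the true quantum position distribution. The centroid
(`centroid()`) is also available; centroid distributions are narrower and
answer a different question, so none of the distribution analyses default
to it.

## Spectra

`compute_vacf()` forms the mass-weighted velocity autocorrelation over all
time origins (FFT-based), normalised to C(0) = 1. `power_spectrum()`
deliberately does not Fourier-transform the ACF: it averages periodograms
of Hann-windowed, 50%-overlapping segments (Welch), so nonnegativity of the
intensity is structural rather than numerical. With a rectangular window
and a single segment the estimator satisfies Parseval exactly - the
spectrum integrates to the mean squared mass-weighted velocity - which is
the package's absolute-normalisation test. The wavenumber resolution is
`1/(c * segment duration)`; peak positions are reported by `band_maximum()`
(ties resolved toward lower wavenumber) and band displacements by
`spectral_shift()`, positive meaning blueshift. Absolute intensities of
velocity power spectra are not physically calibrated quantities here; only
positions and shifts are interpreted, and no a posteriori quantum
correction factors are applied.

## Proton statistics, PMF and transfers

`proton_histogram2d()` normalises the (r_DH, r_HA) histogram to unit
integral so density is in 1/A^2 and an isocontour at an absolute value
(e.g. 1 A^-2) is meaningful across systems. `pmf_from_series()` performs
Boltzmann inversion `A = -kB T log p` on either `r_HA` or the transfer
coordinate `delta = r_DH - r_HA`, masks empty bins and shifts the minimum
to zero. No `r^2` Jacobian is applied by default: the bridge coordinate is
treated as one-dimensional, matching how such profiles are plotted against
a distance axis; a volume-corrected variant is available as an option for
users who want the radial convention. For path-integral input the PMF of
the pooled-bead histogram is the quantum (bead) profile; a centroid-based
profile can be built by passing `centroid()` output instead - both are
legitimate, and they answer different questions, so the package provides
both rather than asserting one.

`locate_minima_barrier()` uses a discrete three-point minimum test
(optional moving-average smoothing, off by default) and reports the barrier
as the highest profile point between the two deepest minima, referenced to
the deeper one. `detect_transfers()` assigns the proton to donor or
acceptor only outside a hysteresis band `|delta| <= h` (default
`h = 0.1` A, about one thermal standard deviation of `delta` in a stiff
well); within the band the previous assignment persists, so thermal
recrossing noise at the barrier top is not counted as transfer events.
Residence fractions are computed over assigned frames and sum to one by
construction.

## Static descriptors

The QTAIM reader ingests tabulated bond-critical-point properties
(rho, its Laplacian, the potential and total energy densities, all in
atomic units; Unicode minus signs are normalised). `espinosa_energy()`
implements the linear estimate `E = |V_BCP|/2`, converted with
627.5095 kcal/mol per hartree; the proportionality constant one-half is the
commonly used calibration of the underlying linear relation, and it
reproduces the tabulated bond energies of the worked examples to within
0.4%, the residual being consistent with the four-decimal rounding of the
printed `V_BCP` inputs. The relation is meaningful only for closed-shell
contacts, so rows with negative Laplacian (shared-shell, covalent bonds)
return `NA`, mirroring the dashes in such tables. `classify_interaction()`
applies the standard sign scheme (Laplacian < 0: covalent; Laplacian > 0
with H_BCP > 0: closed-shell electrostatic; with H_BCP < 0: partially
covalent); magnitudes below 1e-6 a.u. are treated as zero and resolved
toward the electrostatic class with a message, so razor-edge table entries
do not flip classes silently. `sapt_total()`/`audit_sapt()` recompute
component sums, compare them with reported totals at a user tolerance
(printed tables rounded to 3 decimals make ~0.001 kcal/mol discrepancies
normal), and report the sign of the first-order steric balance
`E_elst + E_exch`.

## Trajectory formats and geometry

Two formats are supported: multi-frame XYZ (with an optional `dt=... fs`
token on the comment line) and the CPMD-style TRAJECTORY dialect - step
index, positions in bohr, velocities in atomic units, atom count inferred
from the repetition of step indices. Conversions (0.52917721 A/bohr,
0.02418884 fs per atomic time unit) happen only at the file boundary; all
internal coordinates are A and fs. The stored-frame spacing is
`dt_au * stride`, with the write stride an explicit argument because
trajectory files do not record it. Periodic distances use the crystal
lattice built row-wise with `a` along x and `b` in the xy-plane; the
minimum image is found by wrapping the fractional difference vector and
searching the 27 neighbouring images, exact for cells larger than twice the
distance of interest and verified against an exhaustive image search on a
strongly triclinic cell.

## What the generator does and does not emulate

The synthetic bridge reproduces: thermal bridge geometry fluctuations with
realistic amplitudes, barrier-crossing kinetics, red-shifted stretch bands
on hydrogen bonding, quantum delocalisation and barrier-top enhancement
under path-integral sampling, and the file formats of a plane-wave MD
engine. It does not emulate: anharmonic couplings to the molecular
skeleton, Fermi resonances, dipole intensities, three-dimensional proton
motion off the bridge axis, or ab initio barrier heights - so passing
tests validate the estimators and the pipeline, not any electronic
structure. Barrier magnitudes from the generator are set by its input
parameters, and the quantum-vs-classical comparison is asserted as a
direction (quantum barrier lower), not as the magnitudes a specific
electronic-structure method would give.

## Problem sizes used in the shipped analyses

The bundled analysis scripts and acceptance checks use: classical
double-well runs of 1-2 ns (dt 0.5 fs) for PMF and transfer statistics;
path-integral runs of 100-105 ps (dt 0.1-0.25 fs) at P = 8-32 with
stored-frame strides of 10-25; velocity series of ~2000-8000 stored frames
for spectra. Statistical errors are always block averages (20-25 blocks)
over time, which accounts for serial correlation of MD samples and for the
mutual correlation of beads on one imaginary-time path; raw Poisson errors
would understate histogram uncertainties.
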