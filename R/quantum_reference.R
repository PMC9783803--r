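# Exact quantum references: finite-difference eigensolutions of the 1D
# bridge potentials and closed forms for the (finite-P) harmonic oscillator.

#' Exact thermal position density by grid diagonalisation
#'
#' Diagonalises the 1D Hamiltonian `-hbar^2/(2m) d^2/dx^2 + V(x)` of a
#' harmonic or double-well model on a uniform grid (3-point finite
#' differences) and returns the Boltzmann-weighted position density
#' `sum_n |psi_n|^2 exp(-beta E_n) / Z`, normalised to unit integral on the
#' grid. This is the independent oracle against which the path-integral
#' sampler is validated.
#'
#' The grid is refined once (doubled resolution) and the run aborts if the
#' ground-state energy shifts by more than 1e-6 hartree, so a too-coarse
#' grid cannot silently pass.
#'
#' @param model a [model_potential()] of kind `"harmonic"` or
#'   `"double_well"` (the proton coordinate at fixed donor-acceptor
#'   distance).
#' @param temperature temperature, K.
#' @param grid uniform numeric grid of proton coordinates, A.
#' @param n_states number of eigenstates in the Boltzmann sum.
#' @return data.frame with `x` (A), `density` (1/A); eigenvalues (kcal/mol)
#'   in the `"energies"` attribute.
#' @export
reference_quantum_density <- function(model, temperature, grid, n_states = 40) {
  stopifnot(inherits(model, "model_potential"), temperature > 0)
  if (model$kind == "coupled_bridge")
    stop("reference density is defined for the 1D potentials (fixed R)")
  if (length(grid) < 10 || any(diff(grid) <= 0))
    stop("grid must be increasing with at least 10 points")
  dx <- diff(grid)
  if (max(abs(dx - dx[1])) > 1e-9 * dx[1]) stop("grid must be uniform")

  solve_grid <- function(g, values_only = FALSE) {
    h <- g[2] - g[1]
    m <- model$mass_H * MASSFAC
    tcoef <- HBAR^2 / (2 * m * h^2)
    V <- evaluate_potential(model, g)$energy
    n <- length(g)
    H <- matrix(0, n, n)
    diag(H) <- 2 * tcoef + V
    H[cbind(1:(n - 1), 2:n)] <- -tcoef
    H[cbind(2:n, 1:(n - 1))] <- -tcoef
    eigen(H, symmetric = TRUE, only.values = values_only)
  }

  e0 <- rev(solve_grid(grid, values_only = TRUE)$values)[1]
  fine <- seq(grid[1], grid[length(grid)], length.out = 2L * length(grid) - 1L)
  e0f <- rev(solve_grid(fine, values_only = TRUE)$values)[1]
  if (abs(e0 - e0f) / HARTREE2KCAL > 1e-6)
    stop(sprintf(paste0("resolution error: ground-state energy shifts by ",
                        "%.2e hartree on grid refinement"),
                 abs(e0 - e0f) / HARTREE2KCAL))

  es <- solve_grid(grid)
  ord <- order(es$values)
  vals <- es$values[ord][seq_len(min(n_states, length(ord)))]
  vecs <- es$vectors[, ord[seq_len(length(vals))], drop = FALSE]
  beta <- 1 / (KB * temperature)
  w <- exp(-beta * (vals - vals[1]))
  w <- w / sum(w)
  h <- grid[2] - grid[1]
  dens <- as.numeric((vecs^2) %*% w) / h      # |psi|^2 normalised on the grid
  dens <- dens / sum(dens * h)
  structure(data.frame(x = grid, density = dens),
            energies = vals, class = c("data.frame"))
}

#' Harmonic-oscillator closed forms, continuum and finite-P
#'
#' Reference laws for a 1D harmonic oscillator of mass `mass` (amu) and
#' angular frequency `omega` (fs^-1) at temperature `temperature` (K):
#' `ho_x2_quantum()` and `ho_energy_quantum()` are the continuum
#' (`P -> Inf`) coth laws `<x^2> = hbar/(2 m omega) coth(beta hbar omega/2)`
#' and `<E> = (hbar omega/2) coth(beta hbar omega/2)`;
#' `ho_x2_finiteP()` and `ho_energy_finiteP()` are the exact expectations of
#' the P-bead discretised path (normal-mode sums), i.e. what an exact
#' path-integral sampler with P Trotter replicas converges to, including the
#' Trotter discretisation bias. `P = 1` recovers the classical laws
#' `kBT/(m omega^2)` and `kBT`.
#'
#' @param mass mass, amu.
#' @param omega angular frequency, fs^-1.
#' @param temperature temperature, K.
#' @param P number of Trotter replicas.
#' @return scalar, A^2 or kcal/mol.
#' @export
ho_x2_quantum <- function(mass, omega, temperature) {
  m <- mass * MASSFAC
  beta <- 1 / (KB * temperature)
  HBAR / (2 * m * omega) / tanh(beta * HBAR * omega / 2)
}

#' @rdname ho_x2_quantum
#' @export
ho_energy_quantum <- function(mass, omega, temperature) {
  beta <- 1 / (KB * temperature)
  HBAR * omega / 2 / tanh(beta * HBAR * omega / 2)
}

#' @rdname ho_x2_quantum
#' @export
ho_x2_finiteP <- function(mass, omega, temperature, P) {
  m <- mass * MASSFAC
  beta <- 1 / (KB * temperature)
  wP <- sqrt(P) / (beta * HBAR)
  k <- 0:(P - 1)
  sum(1 / (4 * wP^2 * sin(pi * k / P)^2 + omega^2 / P)) / (beta * m * P)
}

#' @rdname ho_x2_quantum
#' @export
ho_energy_finiteP <- function(mass, omega, temperature, P) {
  beta <- 1 / (KB * temperature)
  k <- 0:(P - 1)
  s2 <- 2 * (1 - cos(2 * pi * k / P))
  mu <- (P / (beta * HBAR^2)) * s2 + beta * omega^2 / P
  mup <- -(P / (beta^2 * HBAR^2)) * s2 + omega^2 / P
  P / (2 * beta) + 0.5 * sum(mup / mu)
}
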