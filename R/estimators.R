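# Path-integral energy estimators and bead-position densities.

block_se <- function(x, n_blocks = 20) {
  n <- length(x)
  n_blocks <- min(n_blocks, n)
  idx <- cut(seq_len(n), n_blocks, labels = FALSE)
  bm <- tapply(x, idx, mean)
  as.numeric(stats::sd(bm) / sqrt(length(bm)))
}

#' Path-integral energy estimators
#'
#' Primitive and centroid-virial estimators of the total quantum energy of
#' the bridge proton from a bead trajectory, with block-averaged standard
#' errors. Both estimate the same finite-P expectation; their agreement on
#' a converged run is a standard internal consistency check.
#'
#' Primitive: `f P/(2 beta) - <sum_k m omega_P^2 (x_k - x_{k+1})^2 / 2>
#' + <sum_k V(x_k)>/P`; centroid-virial: `f/(2 beta)
#' + <sum_k (x_k - x_c) dV/dx_k>/(2P) + <sum_k V(x_k)>/P`, with `f = 1`
#' proton degree of freedom and `omega_P = sqrt(P)/(beta hbar)`.
#'
#' @param btraj a [bead_trajectory()] from [simulate_pimd()].
#' @param model the [model_potential()] that generated it.
#' @param n_blocks blocks for the standard errors (fewer than 10 available
#'   frames per block triggers a warning, not an error).
#' @return list with `primitive`, `primitive_se`, `virial`, `virial_se`
#'   (kcal/mol) and the frame count `n`.
#' @export
energy_estimators <- function(btraj, model, n_blocks = 20) {
  stopifnot(inherits(btraj, "bead_trajectory"), inherits(model, "model_potential"))
  dyn <- attr(btraj, "dynamics")
  if (is.null(dyn)) {
    beads <- sapply(btraj$replicas, function(r) r$positions[, 2, 1] - r$positions[, 3, 1] / 2)
    beads <- matrix(beads, ncol = btraj$P)
    R <- btraj$replicas[[1]]$positions[, 3, 1]
    Tset <- btraj$replicas[[1]]$metadata$temperature
    if (is.null(Tset)) stop("temperature missing from trajectory metadata")
    dyn <- list(beads = beads, R = R, temperature = Tset, mass_H = model$mass_H)
  }
  beads <- dyn$beads
  nf <- nrow(beads); P <- ncol(beads)
  if (nf < 1) stop("empty production segment")
  if (nf < 10 * n_blocks)
    warning("fewer than 10 frames per block; standard errors will be noisy")
  beta <- 1 / (KB * dyn$temperature)
  m <- model$mass_H * MASSFAC
  wP <- sqrt(P) / (beta * HBAR)
  R <- dyn$R
  ev <- cpp_potential(kind_id(model), unclass(model), as.numeric(beads),
                      rep(R, times = P))
  V <- matrix(ev$energy, nf, P)
  dVdx <- -matrix(ev$fx, nf, P)
  vbar <- rowMeans(V)
  # spring term sum_k (x_k - x_{k+1})^2, cyclic
  spring <- if (P == 1) 0 else
    0.5 * m * wP^2 * rowSums((beads - beads[, c(2:P, 1), drop = FALSE])^2)
  xc <- rowMeans(beads)
  virial_t <- rowSums((beads - xc) * dVdx) / (2 * P)
  prim_series <- P / (2 * beta) - spring + vbar
  vir_series <- 1 / (2 * beta) + virial_t + vbar
  list(primitive = mean(prim_series), primitive_se = block_se(prim_series, n_blocks),
       virial = mean(vir_series), virial_se = block_se(vir_series, n_blocks),
       n = nf)
}

#' Pooled-bead position density with blocked errors
#'
#' Histogram density of the proton coordinate pooled over all beads (the
#' quantum position estimator), with a per-bin standard error from block
#' averaging over time, which accounts for serial correlation of the MD
#' samples and for the mutual correlation of beads on one imaginary-time
#' path.
#'
#' @param btraj a [bead_trajectory()] from [simulate_pimd()].
#' @param breaks numeric vector of bin edges, A.
#' @param n_blocks number of time blocks for the standard errors.
#' @return data.frame with `center`, `density` (1/A) and `se`.
#' @export
bead_position_density <- function(btraj, breaks, n_blocks = 20) {
  stopifnot(inherits(btraj, "bead_trajectory"))
  dyn <- attr(btraj, "dynamics")
  beads <- if (!is.null(dyn)) dyn$beads
           else sapply(btraj$replicas,
                       function(r) r$positions[, 2, 1] - r$positions[, 3, 1] / 2)
  beads <- matrix(beads, ncol = btraj$P)
  nf <- nrow(beads)
  idx <- cut(seq_len(nf), n_blocks, labels = FALSE)
  nb <- length(breaks) - 1L
  dens_b <- matrix(0, n_blocks, nb)
  for (b in seq_len(n_blocks)) {
    v <- as.numeric(beads[idx == b, , drop = FALSE])
    ix <- findInterval(v, breaks, rightmost.closed = TRUE)
    cnt <- tabulate(ix[ix >= 1L & ix <= nb], nbins = nb)
    dens_b[b, ] <- cnt / (length(v) * diff(breaks))
  }
  wt <- tabulate(idx, n_blocks) / nf
  dens <- colSums(dens_b * wt)
  se <- apply(dens_b, 2, stats::sd) / sqrt(n_blocks)
  data.frame(center = (breaks[-1] + breaks[-length(breaks)]) / 2,
             density = dens, se = se)
}
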