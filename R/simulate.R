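#' Simulation settings
#'
#' Time step, run length, equilibration split, temperature and thermostat
#' options for the synthetic bridge engines. The equilibration count refers
#' to *stored* frames and is trimmed from the returned trajectory, mirroring
#' the usual practice of excluding the initial segment of an MD run from
#' analysis.
#'
#' @param dt integration time step, fs.
#' @param n_steps number of integration steps.
#' @param n_equil stored frames to discard as equilibration.
#' @param temperature target temperature, K.
#' @param thermostat `"nose_hoover_chain"` or `"none"` (NVE).
#' @param chain_length Nose-Hoover chain length.
#' @param thermostat_time chain relaxation time, fs.
#' @param stride store every `stride`-th step.
#' @param seed integer seed for the Maxwell-Boltzmann velocity draw.
#' @return object of class `sim_settings`.
#' @export
sim_settings <- function(dt = 0.1, n_steps = 10000, n_equil = 0,
                         temperature = 297,
                         thermostat = c("nose_hoover_chain", "none"),
                         chain_length = 4, thermostat_time = 20,
                         stride = 1, seed = 1) {
  thermostat <- match.arg(thermostat)
  stopifnot(dt > 0, n_steps >= 1, stride >= 1, chain_length >= 2,
            thermostat_time > 0)
  if (n_equil >= n_steps %/% stride)
    stop("n_equil must be smaller than the number of stored frames")
  if (thermostat != "none" && temperature <= 0)
    stop("temperature must be positive under a thermostat")
  structure(list(dt = dt, n_steps = as.integer(n_steps),
                 n_equil = as.integer(n_equil), temperature = temperature,
                 thermostat = thermostat, chain_length = as.integer(chain_length),
                 thermostat_time = thermostat_time, stride = as.integer(stride),
                 seed = as.integer(seed)),
            class = "sim_settings")
}

#' Path-integral settings
#'
#' @param P number of Trotter replicas (beads); `P = 1` reduces the
#'   path-integral engine to classical MD.
#' @param bead_thermostat only `"massive_nhc"` (one Nose-Hoover chain per
#'   staging degree of freedom) is provided.
#' @return object of class `path_settings`. The staging spring frequency
#'   `omega_P = sqrt(P)/(beta*hbar)` is derived at run time.
#' @export
path_settings <- function(P = 8, bead_thermostat = "massive_nhc") {
  bead_thermostat <- match.arg(bead_thermostat)
  if (P < 1) stop("configuration error: P must be >= 1")
  structure(list(P = as.integer(P), bead_thermostat = bead_thermostat),
            class = "path_settings")
}

# embed the 1D bridge dynamics as 3 collinear atoms D(0,0,0)-H-A(R,0,0)
embed_bridge <- function(model, x, R, vx = NULL, vR = NULL, dt, meta) {
  nf <- length(x)
  pos <- array(0, c(nf, 3, 3))
  pos[, 2, 1] <- x + R / 2
  pos[, 3, 1] <- R
  vel <- NULL
  if (!is.null(vx)) {
    vel <- array(0, c(nf, 3, 3))
    vel[, 2, 1] <- vx + (if (is.null(vR)) 0 else vR / 2)
    if (!is.null(vR)) vel[, 3, 1] <- vR
  }
  labels <- c("O", "H", "O")
  trajectory(labels, pos, vel, dt = dt, metadata = meta)
}

#' Classical MD on a model potential
#'
#' Velocity-Verlet propagation of the bridge proton (and, for the coupled
#' bridge, the donor-acceptor distance) with optional Nose-Hoover chain
#' thermostatting. Initial velocities are Maxwell-Boltzmann at the target
#' temperature, drawn with the settings seed; identical seeds and settings
#' give bit-identical trajectories.
#'
#' The bridge is embedded in the returned trajectory as three collinear
#' atoms D(0,0,0)-H(x + R/2, 0, 0)-A(R,0,0). The raw dynamical series
#' (proton coordinate, velocities, energies) are attached as the
#' `"dynamics"` attribute.
#'
#' @param model a [model_potential()].
#' @param settings a [sim_settings()].
#' @param x0 initial proton coordinate, A; defaults to a potential minimum.
#' @return a [trajectory()] of the production segment, with velocities.
#' @export
simulate_md <- function(model, settings, x0 = NULL) {
  stopifnot(inherits(model, "model_potential"), inherits(settings, "sim_settings"))
  if (is.null(x0)) x0 <- if (model$kind == "harmonic") 0 else model$a0
  mx <- model$mass_H * MASSFAC
  mR <- model$mass_heavy / 2 * MASSFAC
  raw <- cpp_simulate_md(kind_id(model), unclass(model), mx, mR,
                         settings$dt, settings$n_steps, settings$stride,
                         settings$temperature, KB,
                         settings$thermostat != "none",
                         settings$chain_length, settings$thermostat_time,
                         settings$seed, x0, model$R0)
  dt_store <- settings$dt * settings$stride
  meta <- list(seed = settings$seed, model = model$kind,
               temperature = settings$temperature,
               thermostat = settings$thermostat, dt_integration = settings$dt)
  traj <- embed_bridge(model, raw$x, raw$R, raw$vx, raw$vR, dt_store, meta)
  attr(traj, "dynamics") <- raw
  if (settings$n_equil > 0) {
    traj <- trim_equilibration(traj, settings$n_equil)
    keep <- -seq_len(settings$n_equil)
    attr(traj, "dynamics") <- lapply(raw, `[`, keep)
  }
  traj
}

#' Staging path-integral MD on a model potential
#'
#' Samples the discretised imaginary-time path distribution of the bridge
#' proton with P Trotter replicas, propagated in staging variables with
#' massive Nose-Hoover chains (one chain per staging mode). For the coupled
#' bridge, the heavy donor-acceptor coordinate stays classical and feels
#' the bead-averaged force. `P = 1` is classical MD in different clothing.
#'
#' @param model a [model_potential()].
#' @param settings a [sim_settings()].
#' @param path a [path_settings()].
#' @param x0 initial proton coordinate (all beads collapsed), A.
#' @return a [bead_trajectory()] of P replica trajectories (positions only);
#'   the bead coordinate matrix (frames x P), the heavy-atom series and the
#'   bead-averaged potential are attached as the `"dynamics"` attribute.
#' @export
simulate_pimd <- function(model, settings, path = path_settings(), x0 = NULL) {
  stopifnot(inherits(model, "model_potential"), inherits(settings, "sim_settings"),
            inherits(path, "path_settings"))
  if (is.null(x0)) x0 <- if (model$kind == "harmonic") 0 else model$a0
  mx <- model$mass_H * MASSFAC
  mR <- model$mass_heavy / 2 * MASSFAC
  raw <- cpp_simulate_pimd(kind_id(model), unclass(model), mx, mR, path$P,
                           settings$dt, settings$n_steps, settings$stride,
                           settings$temperature, KB, HBAR,
                           settings$chain_length, settings$thermostat_time,
                           settings$seed, x0, model$R0)
  keep <- if (settings$n_equil > 0) -seq_len(settings$n_equil) else TRUE
  beads <- raw$beads[keep, , drop = FALSE]
  R <- raw$R[keep]
  dt_store <- settings$dt * settings$stride
  meta <- list(seed = settings$seed, model = model$kind, P = path$P,
               temperature = settings$temperature,
               n_equil_trimmed = settings$n_equil)
  reps <- lapply(seq_len(path$P), function(k)
    embed_bridge(model, beads[, k], R, dt = dt_store, meta = meta))
  bt <- bead_trajectory(reps)
  attr(bt, "dynamics") <- list(beads = beads, R = R,
                               epot_mean = raw$epot_mean[keep],
                               temperature = settings$temperature,
                               mass_H = model$mass_H, P = path$P)
  bt
}
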