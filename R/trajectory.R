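#' Trajectory container
#'
#' A trajectory is a set of frames of labelled atomic positions (A) with an
#' optional congruent array of velocities (A/fs), the time between stored
#' frames (fs), an optional periodic cell and a free-form provenance list.
#'
#' @param labels character vector of element symbols, length `n_atoms`.
#' @param positions numeric array `frames x atoms x 3`, A.
#' @param velocities optional array congruent with `positions`, A/fs.
#' @param dt time between stored frames, fs.
#' @param cell optional [cell_parameters()].
#' @param metadata named list of provenance (seed, source file, trims, ...).
#' @return object of class `trajectory`.
#' @export
trajectory <- function(labels, positions, velocities = NULL, dt = 1,
                       cell = NULL, metadata = list()) {
  if (length(dim(positions)) != 3L || dim(positions)[3] != 3L)
    stop("positions must be a frames x atoms x 3 array")
  if (dim(positions)[1] < 1L) stop("a trajectory needs at least one frame")
  if (dim(positions)[2] != length(labels))
    stop("labels length must match the atom dimension of positions")
  if (!is.null(velocities) && !identical(dim(velocities), dim(positions)))
    stop("velocities must be congruent in shape with positions")
  if (dt <= 0) stop("dt must be positive")
  if (!is.null(cell)) stopifnot(inherits(cell, "cell_parameters"))
  structure(list(labels = as.character(labels), positions = positions,
                 velocities = velocities, dt = dt, cell = cell,
                 metadata = metadata),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  d <- dim(x$positions)
  cat(sprintf("<trajectory> %d frames x %d atoms (%s), dt = %g fs%s%s\n",
              d[1], d[2], paste(x$labels, collapse = " "), x$dt,
              if (is.null(x$velocities)) "" else ", with velocities",
              if (is.null(x$cell)) "" else ", periodic"))
  invisible(x)
}

n_frames <- function(traj) dim(traj$positions)[1]

#' Bead (path-integral) trajectory
#'
#' Bundles the P Trotter-replica trajectories of a path-integral run. All
#' replicas share labels, frame spacing and cell.
#'
#' @param replicas list of [trajectory()] objects, one per bead.
#' @return object of class `bead_trajectory`.
#' @export
bead_trajectory <- function(replicas) {
  if (length(replicas) < 1L) stop("need at least one replica")
  for (r in replicas) stopifnot(inherits(r, "trajectory"))
  ref <- dim(replicas[[1]]$positions)
  for (r in replicas) {
    if (!identical(dim(r$positions), ref) ||
        !identical(r$labels, replicas[[1]]$labels))
      stop("replicas must be congruent in shape and share atom labels")
  }
  structure(list(replicas = replicas, P = length(replicas)),
            class = "bead_trajectory")
}

#' @export
print.bead_trajectory <- function(x, ...) {
  cat(sprintf("<bead_trajectory> P = %d replicas of:\n  ", x$P))
  print(x$replicas[[1]])
  invisible(x)
}

#' Drop equilibration frames
#'
#' Removes the first `n_frames` frames of a trajectory and records the trim
#' in the metadata, mirroring the usual split of an MD run into an
#' equilibration segment and a production segment.
#'
#' @param traj a [trajectory()].
#' @param n_frames number of leading frames to discard (`0` is a no-op).
#' @return the trimmed [trajectory()].
#' @export
trim_equilibration <- function(traj, n_frames) {
  stopifnot(inherits(traj, "trajectory"))
  nf <- dim(traj$positions)[1]
  if (n_frames < 0) stop("n_frames must be >= 0")
  if (n_frames >= nf)
    stop(sprintf("cannot trim %d frames from a %d-frame trajectory", n_frames, nf))
  if (n_frames == 0) return(traj)
  keep <- seq.int(n_frames + 1L, nf)
  traj$positions <- traj$positions[keep, , , drop = FALSE]
  if (!is.null(traj$velocities))
    traj$velocities <- traj$velocities[keep, , , drop = FALSE]
  traj$metadata$n_equil_trimmed <-
    sum(traj$metadata$n_equil_trimmed, n_frames)
  traj
}

#' Centroid of a bead trajectory
#'
#' Per-atom arithmetic mean over the P replicas, frame by frame: the
#' path-integral centroid. `P = 1` returns the single replica unchanged.
#'
#' @param btraj a [bead_trajectory()].
#' @return a [trajectory()].
#' @export
centroid <- function(btraj) {
  stopifnot(inherits(btraj, "bead_trajectory"))
  if (btraj$P == 1L) return(btraj$replicas[[1]])
  out <- btraj$replicas[[1]]
  acc <- out$positions
  for (k in 2:btraj$P) acc <- acc + btraj$replicas[[k]]$positions
  out$positions <- acc / btraj$P
  out$velocities <- NULL
  out$metadata$centroid_of_P <- btraj$P
  out
}
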