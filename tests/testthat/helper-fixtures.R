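# Shared helpers: constants mirrored from the package internals and small
# constructors for synthetic trajectories.

kB <- 0.0019872041           # kcal/mol/K
hbar_kcal_fs <- 1.054571817e-34 * 6.02214076e23 / 4184 * 1e15
massfac <- 1e7 / 4184        # amu -> kcal/mol fs^2/A^2
c_cmfs <- 2.99792458e-5      # speed of light, cm/fs

# trajectory with prescribed x-velocity series for each atom (list of vectors)
velocity_trajectory <- function(vlist, labels = rep("H", length(vlist)), dt = 0.25) {
  n <- length(vlist[[1]])
  na <- length(vlist)
  pos <- array(0, c(n, na, 3))
  vel <- array(0, c(n, na, 3))
  for (a in seq_len(na)) vel[, a, 1] <- vlist[[a]]
  trajectory(labels, pos, vel, dt = dt)
}

# collinear D-H-A geometry series embedded as a 3-atom trajectory
bridge_series_trajectory <- function(r_DH, r_DA, dt = 1) {
  n <- length(r_DH)
  pos <- array(0, c(n, 3, 3))
  pos[, 2, 1] <- r_DH
  pos[, 3, 1] <- r_DA
  trajectory(c("O", "H", "O"), pos, dt = dt)
}

# hb_geometry straight from a transfer coordinate xi = r_DH - r_HA
# (constant r_DA, collinear)
series_from_xi <- function(xi, r_DA = 2.6, dt = 1) {
  r_DH <- (r_DA + xi) / 2
  out <- data.frame(time = (seq_along(xi) - 1) * dt,
                    r_DH = r_DH, r_HA = r_DA - r_DH,
                    r_DA = rep(r_DA, length(xi)))
  class(out) <- c("hb_geometry", "data.frame")
  out
}

# literal two-threshold reference state machine for proton-transfer counting
reference_transfer_machine <- function(xi, h) {
  state <- 0L; events <- 0L; nd <- 0L; na <- 0L
  for (v in xi) {
    new <- if (v < -h) -1L else if (v > h) 1L else state
    if (state != 0L && new != state) events <- events + 1L
    state <- new
    if (state == -1L) nd <- nd + 1L
    if (state == 1L) na <- na + 1L
  }
  list(n_events = events,
       residence_donor = if (nd + na) nd / (nd + na) else NA_real_)
}

# brute-force periodic distance: exhaustive search over an 11x11x11 block
# of images of the raw difference vector (wide enough for points several
# cells apart)
brute_force_image_distance <- function(p1, p2, cell) {
  lat <- cell$lattice
  d <- p2 - p1
  sh <- as.matrix(expand.grid(-5:5, -5:5, -5:5))
  img <- matrix(d, nrow = nrow(sh), ncol = 3, byrow = TRUE) + sh %*% lat
  sqrt(min(rowSums(img^2)))
}

# blocked standard error (duplicated deliberately as an independent check)
blocked_se <- function(x, nb = 20) {
  idx <- cut(seq_along(x), nb, labels = FALSE)
  bm <- tapply(x, idx, mean)
  sd(bm) / sqrt(length(bm))
}

triclinic_cell <- function() cell_parameters(6.910, 12.289, 12.647,
                                             112.713, 93.424, 103.103)
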