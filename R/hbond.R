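# Bridge geometry series, proton-position histograms, potentials of mean
# force and proton-transfer statistics.

#' Define a D-H...A bridge
#'
#' @param donor_index,hydrogen_index,acceptor_index distinct atom indices.
#' @param label free-form label (e.g. `"OD1"`).
#' @return object of class `bridge_definition`.
#' @export
bridge_definition <- function(donor_index, hydrogen_index, acceptor_index,
                              label = "bridge") {
  idx <- c(donor_index, hydrogen_index, acceptor_index)
  if (anyDuplicated(idx)) stop("selection error: bridge indices must be distinct")
  if (any(idx < 1)) stop("selection error: indices must be positive")
  structure(list(donor_index = donor_index, hydrogen_index = hydrogen_index,
                 acceptor_index = acceptor_index, label = label),
            class = "bridge_definition")
}

#' Per-frame bridge distances
#'
#' r(D-H), r(H...A) and r(D...A) for one bridge over a trajectory, using
#' minimum-image distances when a cell is present. For a bead trajectory
#' the replicas are pooled frame-by-frame (the quantum position estimator),
#' giving `P * n_frames` rows.
#'
#' @param traj a [trajectory()] or [bead_trajectory()].
#' @param bridge a [bridge_definition()].
#' @param cell optional [cell_parameters()] overriding the trajectory cell.
#' @return object of class `hb_geometry`: data.frame with `time` (fs),
#'   `r_DH`, `r_HA`, `r_DA` (A).
#' @export
distance_series <- function(traj, bridge, cell = NULL) {
  stopifnot(inherits(bridge, "bridge_definition"))
  if (inherits(traj, "bead_trajectory")) {
    parts <- lapply(traj$replicas, distance_series, bridge = bridge, cell = cell)
    out <- do.call(rbind, parts)
    class(out) <- c("hb_geometry", "data.frame")
    return(out)
  }
  stopifnot(inherits(traj, "trajectory"))
  idx <- c(bridge$donor_index, bridge$hydrogen_index, bridge$acceptor_index)
  if (any(idx > length(traj$labels)))
    stop("selection error: bridge index out of range")
  if (is.null(cell)) cell <- traj$cell
  nf <- n_frames(traj)
  pd <- traj$positions[, bridge$donor_index, , drop = FALSE]
  ph <- traj$positions[, bridge$hydrogen_index, , drop = FALSE]
  pa <- traj$positions[, bridge$acceptor_index, , drop = FALSE]
  dim(pd) <- dim(ph) <- dim(pa) <- c(nf, 3)
  dist2 <- function(p, q) {
    if (is.null(cell)) sqrt(rowSums((p - q)^2))
    else vapply(seq_len(nf), function(i)
      minimum_image_distance(p[i, ], q[i, ], cell), numeric(1))
  }
  out <- data.frame(time = (seq_len(nf) - 1) * traj$dt,
                    r_DH = dist2(pd, ph), r_HA = dist2(ph, pa),
                    r_DA = dist2(pd, pa))
  class(out) <- c("hb_geometry", "data.frame")
  out
}

#' 2D proton-position histogram
#'
#' Probability density over (r(D-H), r(H...A)) normalised to unit integral,
#' so the density unit is 1/A^2 and isocontours can be drawn at an absolute
#' density value. Pooled bead input (all P replicas) is the quantum
#' position estimator.
#'
#' @param series an `hb_geometry` from [distance_series()].
#' @param bin_width bin width on both axes, A.
#' @return object of class `histogram2d`: list with `x_edges`, `y_edges`,
#'   `density` (matrix, 1/A^2) and `counts`.
#' @export
proton_histogram2d <- function(series, bin_width = 0.02) {
  stopifnot(inherits(series, "hb_geometry"))
  if (nrow(series) == 0) stop("data error: empty series")
  if (bin_width <= 0) stop("range error: bin_width must be positive")
  xe <- seq(floor(min(series$r_DH) / bin_width) * bin_width,
            ceiling(max(series$r_DH) / bin_width + 1e-9) * bin_width,
            by = bin_width)
  ye <- seq(floor(min(series$r_HA) / bin_width) * bin_width,
            ceiling(max(series$r_HA) / bin_width + 1e-9) * bin_width,
            by = bin_width)
  if (length(xe) < 2) xe <- c(xe, xe + bin_width)
  if (length(ye) < 2) ye <- c(ye, ye + bin_width)
  ix <- pmin(pmax(findInterval(series$r_DH, xe, rightmost.closed = TRUE), 1L),
             length(xe) - 1L)
  iy <- pmin(pmax(findInterval(series$r_HA, ye, rightmost.closed = TRUE), 1L),
             length(ye) - 1L)
  counts <- matrix(0, length(xe) - 1L, length(ye) - 1L)
  for (k in seq_along(ix)) counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1
  dens <- counts / (nrow(series) * bin_width^2)
  structure(list(x_edges = xe, y_edges = ye, density = dens, counts = counts,
                 n = nrow(series), bin_width = bin_width),
            class = "histogram2d")
}

#' Potential of mean force by Boltzmann inversion
#'
#' `A(xi) = -kB T log p(xi)` from a histogram of the chosen bridge
#' coordinate, shifted so the minimum of the defined values is zero. Bins
#' with no counts are masked (NA). The proton coordinate is treated as a
#' 1D bridge coordinate, so no r^2 Jacobian is applied by default; set
#' `jacobian = TRUE` to divide the density by `xi^2` first (only meaningful
#' for the `r_HA` coordinate).
#'
#' @param series an `hb_geometry` from [distance_series()].
#' @param coordinate `"r_HA"` or `"delta"` (`r_DH - r_HA`).
#' @param n_bins number of bins (ignored when `breaks` is given).
#' @param temperature temperature, K.
#' @param breaks optional explicit bin edges, A.
#' @param jacobian apply the r^2 volume correction (default FALSE).
#' @return object of class `pmf_profile`: data.frame with `center` (A),
#'   `free_energy` (kcal/mol, NA where empty) and `counts`; temperature and
#'   coordinate name as attributes.
#' @export
pmf_from_series <- function(series, coordinate = c("r_HA", "delta"),
                            n_bins = 50, temperature = 297, breaks = NULL,
                            jacobian = FALSE) {
  stopifnot(inherits(series, "hb_geometry"))
  coordinate <- match.arg(coordinate)
  if (temperature <= 0) stop("temperature must be positive")
  xi <- if (coordinate == "r_HA") series$r_HA else series$r_DH - series$r_HA
  if (is.null(breaks)) breaks <- seq(min(xi), max(xi), length.out = n_bins + 1)
  ix <- findInterval(xi, breaks, rightmost.closed = TRUE)
  nb <- length(breaks) - 1L
  counts <- tabulate(ix[ix >= 1L & ix <= nb], nbins = nb)
  if (sum(counts > 0) < 2) stop("data error: fewer than 2 occupied bins")
  dens <- counts / (sum(counts) * diff(breaks))
  if (jacobian) {
    centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
    dens <- dens / centers^2
    dens <- dens / sum(dens * diff(breaks), na.rm = TRUE)
  }
  A <- ifelse(counts > 0, -KB * temperature * log(dens), NA_real_)
  A <- A - min(A, na.rm = TRUE)
  out <- data.frame(center = (breaks[-1] + breaks[-length(breaks)]) / 2,
                    free_energy = A, counts = counts)
  attr(out, "temperature") <- temperature
  attr(out, "coordinate") <- coordinate
  class(out) <- c("pmf_profile", "data.frame")
  out
}

#' Minima and transfer barrier of a PMF profile
#'
#' Local minima by a discrete three-point test after optional moving-average
#' smoothing; the barrier is the highest point of the profile between the
#' two deepest minima, referenced to the deeper of the two. A profile with
#' fewer than two minima returns `barrier = NA`.
#'
#' @param pmf a `pmf_profile` from [pmf_from_series()].
#' @param smooth_window odd moving-average width in bins (0 = no smoothing).
#' @return list with `minima` (data.frame: position A, value kcal/mol),
#'   `barrier` (kcal/mol or NA) and `saddle` (position of the barrier top).
#' @export
locate_minima_barrier <- function(pmf, smooth_window = 0) {
  stopifnot(inherits(pmf, "pmf_profile"))
  ok <- !is.na(pmf$free_energy)
  if (!any(ok)) stop("data error: all bins are masked")
  if (sum(ok) < 3) stop("data error: need at least 3 defined bins")
  x <- pmf$center[ok]
  y <- pmf$free_energy[ok]
  if (smooth_window > 1) {
    k <- min(smooth_window, length(y) - (1 - length(y) %% 2))
    if (k %% 2 == 0) k <- k - 1
    y <- stats::filter(y, rep(1 / k, k), sides = 2)
    pad <- is.na(y)
    y[pad] <- pmf$free_energy[ok][pad]
    y <- as.numeric(y)
  }
  n <- length(y)
  is_min <- c(y[1] < y[2],
              y[2:(n - 1)] <= y[1:(n - 2)] & y[2:(n - 1)] < y[3:n],
              y[n] < y[n - 1])
  mins <- data.frame(position = x[is_min], value = y[is_min])
  barrier <- NA_real_; saddle <- NA_real_
  if (nrow(mins) >= 2) {
    two <- mins[order(mins$value)[1:2], ]
    i1 <- which(x == min(two$position)); i2 <- which(x == max(two$position))
    seg <- i1:i2
    top <- seg[which.max(y[seg])]
    barrier <- y[top] - min(two$value)
    saddle <- x[top]
  }
  list(minima = mins, barrier = barrier, saddle = saddle)
}

#' Proton-transfer detection with hysteresis
#'
#' The transfer coordinate is `xi = r_DH - r_HA`. The proton is assigned to
#' the donor while `xi < -h` and to the acceptor while `xi > +h`; within
#' the band the previous assignment persists, so rapid recrossings around
#' `xi = 0` are not counted. Events are confirmed state changes only.
#' Residence fractions are computed over assigned frames and sum to one
#' exactly.
#'
#' @param series an `hb_geometry` from [distance_series()].
#' @param hysteresis half-width `h` of the dead band, A (`>= 0`).
#' @return object of class `transfer_events`: list with `event_times` (fs),
#'   `n_events`, `residence_donor`, `residence_acceptor`, `hysteresis`.
#' @export
detect_transfers <- function(series, hysteresis = 0.1) {
  stopifnot(inherits(series, "hb_geometry"))
  if (hysteresis < 0) stop("hysteresis must be >= 0")
  xi <- series$r_DH - series$r_HA
  h <- hysteresis
  state <- 0L                      # 0 unassigned, -1 donor, +1 acceptor
  n_assigned_donor <- 0L; n_assigned_acceptor <- 0L
  events <- numeric(0)
  for (i in seq_along(xi)) {
    new <- state
    if (xi[i] < -h) new <- -1L
    else if (xi[i] > h) new <- 1L
    if (new != state && state != 0L) events <- c(events, series$time[i])
    state <- new
    if (state == -1L) n_assigned_donor <- n_assigned_donor + 1L
    if (state == 1L) n_assigned_acceptor <- n_assigned_acceptor + 1L
  }
  n_assigned <- n_assigned_donor + n_assigned_acceptor
  structure(list(event_times = events, n_events = length(events),
                 residence_donor = if (n_assigned) n_assigned_donor / n_assigned else NA_real_,
                 residence_acceptor = if (n_assigned) n_assigned_acceptor / n_assigned else NA_real_,
                 hysteresis = h),
            class = "transfer_events")
}

#' @export
print.transfer_events <- function(x, ...) {
  cat(sprintf("<transfer_events> %d events, residence donor %.3f / acceptor %.3f (h = %g A)\n",
              x$n_events, x$residence_donor, x$residence_acceptor, x$hysteresis))
  invisible(x)
}
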