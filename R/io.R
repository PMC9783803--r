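#' Triclinic cell parameters
#'
#' Crystallographic cell from lengths and angles. The lattice matrix is
#' built row-wise with `a` along x and `b` in the xy-plane, so a point's
#' Cartesian coordinates are `fractional %*% lattice`.
#'
#' @param a,b,c cell lengths, A.
#' @param alpha,beta,gamma cell angles, degrees.
#' @return object of class `cell_parameters` with a `lattice` attribute.
#' @examples
#' cell_parameters(6.910, 12.289, 12.647, 112.713, 93.424, 103.103)
#' @export
cell_parameters <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  stopifnot(a > 0, b > 0, c > 0)
  if (any(c(alpha, beta, gamma) <= 0) || any(c(alpha, beta, gamma) >= 180))
    stop("cell angles must lie in (0, 180) degrees")
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180)
  cg <- cos(gamma * pi / 180); sg <- sin(gamma * pi / 180)
  cx <- c * cb
  cy <- c * (ca - cb * cg) / sg
  cz2 <- c^2 - cx^2 - cy^2
  if (cz2 <= 0) stop("degenerate cell: volume <= 0")
  lat <- rbind(c(a, 0, 0),
               c(b * cg, b * sg, 0),
               c(cx, cy, sqrt(cz2)))
  vol <- det(lat)
  if (vol <= 0) stop("degenerate cell: volume <= 0")
  structure(list(a = a, b = b, c = c,
                 alpha = alpha, beta = beta, gamma = gamma,
                 lattice = lat, volume = vol),
            class = "cell_parameters")
}

#' @export
print.cell_parameters <- function(x, ...) {
  cat(sprintf("<cell> a=%.3f b=%.3f c=%.3f A, alpha=%.2f beta=%.2f gamma=%.2f deg, V=%.2f A^3\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, x$volume))
  invisible(x)
}

#' Minimum-image distance
#'
#' Shortest distance between two points under periodic boundary conditions,
#' found over the 27 nearest periodic images after wrapping the difference
#' vector into the central cell (exact for any cell whose lengths exceed
#' twice the interaction range, the usual simulation regime). Without a
#' cell, the plain Euclidean distance.
#'
#' @param p1,p2 numeric length-3 Cartesian points, A.
#' @param cell optional [cell_parameters()].
#' @return distance in A.
#' @export
minimum_image_distance <- function(p1, p2, cell = NULL) {
  d <- as.numeric(p2) - as.numeric(p1)
  if (is.null(cell)) return(sqrt(sum(d^2)))
  stopifnot(inherits(cell, "cell_parameters"))
  lat <- cell$lattice
  f <- d %*% solve(lat)
  f <- f - round(f)
  sh <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  img <- (matrix(f, nrow = 27, ncol = 3, byrow = TRUE) + sh) %*% lat
  sqrt(min(rowSums(img^2)))
}

#' Read a CPMD-style TRAJECTORY file
#'
#' Whitespace-delimited lines of step index, three position columns (bohr)
#' and three velocity columns (atomic units); the atom count is inferred
#' from the repetition of step indices. Positions are converted to A,
#' velocities to A/fs, and the stored frame spacing is
#' `dt_au * 0.02418884 fs * stride`.
#'
#' @param path file path.
#' @param dt_au integration time step in atomic units of time.
#' @param stride file-write interval in integration steps.
#' @param labels optional element labels (defaults to `X1..Xn`).
#' @param cell optional [cell_parameters()].
#' @return a [trajectory()] with velocities.
#' @export
read_cpmd_trajectory <- function(path, dt_au = 3, stride = 1, labels = NULL,
                                 cell = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("format error: empty TRAJECTORY file")
  toks <- strsplit(trimws(lines), "\\s+")
  ncol <- lengths(toks)
  bad <- which(ncol != 7L)
  if (length(bad))
    stop(sprintf("format error: expected 7 columns at line %d, found %d",
                 bad[1], ncol[bad[1]]))
  m <- matrix(as.numeric(unlist(toks)), ncol = 7, byrow = TRUE)
  if (anyNA(m)) stop("format error: non-numeric field in TRAJECTORY file")
  steps <- m[, 1]
  n_at <- rle(steps)$lengths[1]
  n_full <- nrow(m) %/% n_at
  if (nrow(m) %% n_at != 0) {
    warning(sprintf("dropping malformed trailing partial frame (%d lines)",
                    nrow(m) %% n_at))
    m <- m[seq_len(n_full * n_at), , drop = FALSE]
    steps <- m[, 1]
  }
  frame_of <- rep(seq_len(n_full), each = n_at)
  per_frame <- rle(steps)$lengths
  if (any(per_frame != n_at)) {
    off <- cumsum(per_frame)[which(per_frame != n_at)[1] - 1] + 1
    stop(sprintf("format error: inconsistent atoms per frame near line %d", off))
  }
  pos <- array(NA_real_, c(n_full, n_at, 3))
  vel <- array(NA_real_, c(n_full, n_at, 3))
  for (j in 1:3) {
    pos[, , j] <- matrix(m[, 1 + j], nrow = n_full, byrow = TRUE) * BOHR2ANG
    vel[, , j] <- matrix(m[, 4 + j], nrow = n_full, byrow = TRUE) *
      (BOHR2ANG / AUT2FS)
  }
  if (is.null(labels)) labels <- paste0("X", seq_len(n_at))
  trajectory(labels, pos, vel, dt = dt_au * AUT2FS * stride, cell = cell,
             metadata = list(source = path, dt_au = dt_au, stride = stride))
}

#' Write a CPMD-style TRAJECTORY file
#'
#' Inverse of [read_cpmd_trajectory()]: positions in bohr, velocities in
#' atomic units, one line per atom per frame. Missing velocities are
#' written as zeros.
#'
#' @param traj a [trajectory()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cpmd_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  nf <- n_frames(traj); na <- length(traj$labels)
  vel <- traj$velocities
  if (is.null(vel)) vel <- array(0, dim(traj$positions))
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_len(nf)) {
    p <- traj$positions[i, , , drop = FALSE] / BOHR2ANG
    v <- vel[i, , , drop = FALSE] / (BOHR2ANG / AUT2FS)
    writeLines(sprintf(" %8d %18.10f %18.10f %18.10f %18.10f %18.10f %18.10f",
                       i, p[1, , 1], p[1, , 2], p[1, , 3],
                       v[1, , 1], v[1, , 2], v[1, , 3]), con)
  }
  invisible(path)
}

#' Read / write multi-frame XYZ
#'
#' Standard XYZ: an atom-count line, a comment line, then `element x y z`
#' in A. A `dt=<value> fs` token on the comment line is parsed into the
#' trajectory's frame spacing.
#'
#' @param path file path.
#' @return a [trajectory()] (positions only).
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  i <- 1L; n <- length(lines)
  frames <- list(); labels <- NULL; dt <- NA_real_
  while (i <= n) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    na <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(na) || na < 1)
      stop(sprintf("format error: bad atom-count line at line %d", i))
    if (i + 1L + na > n)
      stop(sprintf("format error: truncated frame starting at line %d", i))
    comment <- lines[i + 1L]
    mm <- regmatches(comment, regexec("dt=([0-9.eE+-]+)\\s*fs", comment))[[1]]
    if (length(mm) == 2) dt <- as.numeric(mm[2])
    body <- lines[(i + 2L):(i + 1L + na)]
    toks <- strsplit(trimws(body), "\\s+")
    if (any(lengths(toks) < 4))
      stop(sprintf("format error: short atom line in frame starting at line %d", i))
    lab <- vapply(toks, `[[`, "", 1L)
    xyz <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3)))
    if (anyNA(xyz))
      stop(sprintf("format error: non-numeric coordinate in frame at line %d", i))
    if (is.null(labels)) labels <- lab
    else if (!identical(lab, labels))
      stop(sprintf("format error: atom labels change at line %d", i))
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 2L + na
  }
  if (!length(frames)) stop("format error: empty XYZ file")
  pos <- array(NA_real_, c(length(frames), length(labels), 3))
  for (k in seq_along(frames)) pos[k, , ] <- frames[[k]]
  meta <- list(source = path)
  trajectory(labels, pos, dt = if (is.na(dt)) 1 else dt, metadata = meta)
}

#' @rdname read_xyz
#' @param traj a [trajectory()].
#' @export
write_xyz <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  nf <- n_frames(traj); na <- length(traj$labels)
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_len(nf)) {
    writeLines(as.character(na), con)
    writeLines(sprintf("frame %d dt=%g fs", i, traj$dt), con)
    writeLines(sprintf("%-3s %15.8f %15.8f %15.8f", traj$labels,
                       traj$positions[i, , 1], traj$positions[i, , 2],
                       traj$positions[i, , 3]), con)
  }
  invisible(path)
}

#' Write the replicas of a bead trajectory to per-replica files
#'
#' Files are suffixed `_k` for k = 1..P before the extension.
#'
#' @param btraj a [bead_trajectory()].
#' @param path base path, e.g. `"run.xyz"` gives `run_1.xyz`, ...
#' @param format `"xyz"` or `"cpmd"`.
#' @return character vector of written paths, invisibly.
#' @export
write_bead_trajectory <- function(btraj, path, format = c("xyz", "cpmd")) {
  stopifnot(inherits(btraj, "bead_trajectory"))
  format <- match.arg(format)
  ext <- tools::file_ext(path)
  base <- if (nzchar(ext)) sub(paste0("\\.", ext, "$"), "", path) else path
  paths <- character(btraj$P)
  for (k in seq_len(btraj$P)) {
    pk <- paste0(base, "_", k, if (nzchar(ext)) paste0(".", ext) else "")
    if (format == "xyz") write_xyz(btraj$replicas[[k]], pk)
    else write_cpmd_trajectory(btraj$replicas[[k]], pk)
    paths[k] <- pk
  }
  invisible(paths)
}
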