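# Velocity autocorrelation functions and vibrational power spectra.

sel_indices <- function(traj, selection) {
  if (is.character(selection)) {
    idx <- which(traj$labels %in% selection)
  } else idx <- as.integer(selection)
  if (length(idx) == 0) stop("selection error: empty atom selection")
  if (any(idx < 1 | idx > length(traj$labels)))
    stop("selection error: atom index out of range")
  idx
}

atomic_masses <- function(labels) {
  tab <- c(H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999,
           F = 18.998, X = 1)
  m <- tab[sub("[0-9]+$", "", labels)]
  m[is.na(m)] <- 1
  unname(m)
}

# autocorrelation sum_t v_t v_{t+j} for j = 0..lag via FFT, normalised per origin
acf_fft <- function(v, n_lag) {
  n <- length(v)
  np <- 2^ceiling(log2(2 * n))
  f <- stats::fft(c(v, rep(0, np - n)))
  ac <- Re(stats::fft(f * Conj(f), inverse = TRUE)) / np
  ac[seq_len(n_lag + 1)] / (n - 0:n_lag)
}

#' Velocity autocorrelation function
#'
#' Mass-weighted velocity autocorrelation
#' `C(tau) = sum_i m_i <v_i(t) . v_i(t+tau)>_t` over the selected atoms,
#' averaged over all valid time origins and normalised so `C(0) = 1`. Its
#' Fourier transform is the vibrational density of states; the normalised
#' VACF of a single harmonic mode is `cos(omega tau)`.
#'
#' @param traj a [trajectory()] with velocities.
#' @param selection atom indices or element labels; defaults to all atoms.
#' @param max_lag maximum lag, fs (at most half the trajectory length).
#' @param mass_weighted weight each atom by its mass (default TRUE).
#' @return object of class `vacf` with `lags` (fs) and `values`.
#' @export
compute_vacf <- function(traj, selection = seq_along(traj$labels),
                         max_lag = NULL, mass_weighted = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  if (is.null(traj$velocities)) stop("data error: trajectory has no velocities")
  idx <- sel_indices(traj, selection)
  nf <- n_frames(traj)
  span <- (nf - 1) * traj$dt
  if (is.null(max_lag)) max_lag <- span / 2
  if (max_lag > span / 2 + 1e-9)
    stop("max_lag must not exceed half the trajectory length")
  n_lag <- floor(max_lag / traj$dt)
  masses <- atomic_masses(traj$labels)
  acc <- numeric(n_lag + 1)
  for (i in idx) for (j in 1:3) {
    w <- if (mass_weighted) masses[i] else 1
    acc <- acc + w * acf_fft(traj$velocities[, i, j], n_lag)
  }
  if (acc[1] <= 0) stop("data error: zero-velocity selection, cannot normalise")
  structure(list(lags = (0:n_lag) * traj$dt, values = acc / acc[1],
                 selection = idx, mass_weighted = mass_weighted),
            class = "vacf")
}

#' Vibrational power spectrum of atomic velocities
#'
#' Welch-averaged periodogram of the (optionally mass-weighted) Cartesian
#' velocity components of the selected atoms, summed over atoms and
#' components: the vibrational density of states on a wavenumber axis.
#' Segments overlap by 50%; the default window is Hann. Intensities are
#' nonnegative by construction. With a rectangular window and one segment
#' the integral of the spectrum over wavenumber equals the mean squared
#' (mass-weighted) velocity of the selection (Parseval), so intensity
#' carries units of amu (A/fs)^2 per cm^-1.
#'
#' @param traj a [trajectory()] with velocities.
#' @param selection atom indices or element labels; defaults to all atoms.
#' @param window `"hann"` or `"rect"`.
#' @param n_segments number of 50%-overlapping segments (1 = plain
#'   periodogram of the full series).
#' @param mass_weighted weight each atom's contribution by its mass.
#' @return object of class `power_spectrum` with `wavenumbers` (cm^-1,
#'   strictly increasing), `intensity`, and `resolution = 1/(c * segment
#'   duration)`.
#' @export
power_spectrum <- function(traj, selection = seq_along(traj$labels),
                           window = c("hann", "rect"), n_segments = 1,
                           mass_weighted = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  if (is.null(traj$velocities)) stop("data error: trajectory has no velocities")
  window <- match.arg(window)
  idx <- sel_indices(traj, selection)
  nf <- n_frames(traj)
  if (n_segments < 1) stop("n_segments must be >= 1")
  L <- floor(2 * nf / (n_segments + 1))
  if (L < 2) stop("range error: segment longer than the production run")
  starts <- floor(seq(0, nf - L, length.out = n_segments))
  w <- if (window == "hann") 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / (L - 1))
       else rep(1, L)
  wnorm <- sum(w^2)
  masses <- atomic_masses(traj$labels)
  nk <- L %/% 2 + 1
  psd <- numeric(nk)
  for (s in starts) {
    seg <- traj$velocities[s + seq_len(L), idx, , drop = FALSE]
    for (a in seq_along(idx)) for (j in 1:3) {
      v <- seg[, a, j] * w
      pk <- Mod(stats::fft(v))^2 * traj$dt / wnorm   # two-sided PSD, units/fs^-1
      one <- pk[seq_len(nk)]
      fold <- c(1, rep(2, nk - 2), if (L %% 2 == 0) 1 else 2)
      one <- one * fold
      wt <- if (mass_weighted) masses[idx[a]] else 1
      psd <- psd + wt * one
    }
  }
  psd <- psd / n_segments
  dnu <- 1 / (C_CMFS * L * traj$dt)              # resolution, cm^-1
  structure(list(wavenumbers = (0:(nk - 1)) * dnu,
                 intensity = psd * C_CMFS,        # per cm^-1 instead of per fs^-1
                 resolution = dnu, selection = idx, window = window,
                 n_segments = n_segments, mass_weighted = mass_weighted),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %d bins, 0..%.0f cm^-1, resolution %.2f cm^-1 (%s window, %d segment%s)\n",
              length(x$wavenumbers), max(x$wavenumbers), x$resolution,
              x$window, x$n_segments, if (x$n_segments > 1) "s" else ""))
  invisible(x)
}

#' Band maximum of a power spectrum
#'
#' Position and height of the intensity maximum on a wavenumber window;
#' ties break toward the lower wavenumber.
#'
#' @param spec a [power_spectrum()].
#' @param lo,hi window bounds, cm^-1 (must lie within the spectrum axis).
#' @return list with `wavenumber` (cm^-1) and `height`.
#' @export
band_maximum <- function(spec, lo, hi) {
  stopifnot(inherits(spec, "power_spectrum"))
  if (lo > hi) stop("range error: lo > hi")
  sel <- which(spec$wavenumbers >= lo & spec$wavenumbers <= hi)
  if (!length(sel)) stop("range error: empty wavenumber window")
  i <- sel[which.max(spec$intensity[sel])]
  list(wavenumber = spec$wavenumbers[i], height = spec$intensity[i])
}

#' Band shift between two spectra
#'
#' `band_maximum(spec_b) - band_maximum(spec_a)` on a common window:
#' positive means a blueshift of `b` relative to `a`, negative a redshift
#' (the usual signature of X-H stretching on hydrogen-bond formation).
#'
#' @param spec_a,spec_b [power_spectrum()] objects covering the window.
#' @param lo,hi window bounds, cm^-1.
#' @return shift in cm^-1.
#' @export
spectral_shift <- function(spec_a, spec_b, lo, hi) {
  band_maximum(spec_b, lo, hi)$wavenumber - band_maximum(spec_a, lo, hi)$wavenumber
}

#' Export a spectrum or VACF as two-column CSV
#'
#' @param x a [power_spectrum()] or [compute_vacf()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(x, path) {
  if (inherits(x, "power_spectrum"))
    df <- data.frame(wavenumber_cm1 = x$wavenumbers, intensity = x$intensity)
  else if (inherits(x, "vacf"))
    df <- data.frame(lag_fs = x$lags, vacf = x$values)
  else stop("x must be a power_spectrum or vacf")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
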