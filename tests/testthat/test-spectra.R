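# Velocity autocorrelation functions and power spectra.

mode_velocity <- function(nu_cm, n, dt, phase = 0)
  cos(2 * pi * c_cmfs * nu_cm * (0:(n - 1)) * dt + phase)

test_that("the VACF of a single harmonic mode is cos(omega tau)", {
  dt <- 0.1; n <- 200000; w <- 0.6405
  tr <- velocity_trajectory(list(cos(w * (0:(n - 1)) * dt)), dt = dt)
  vc <- compute_vacf(tr, max_lag = 5 * 2 * pi / w)
  expect_equal(vc$values[1], 1)
  expect_lt(sqrt(mean((vc$values - cos(w * vc$lags))^2)), 1e-3)
  expect_lte(max(abs(vc$values)), 1 + 1e-9)

  const <- velocity_trajectory(list(rep(2, 1000)), dt = dt)
  expect_equal(compute_vacf(const, max_lag = 10)$values, rep(1, 101))
})

test_that("white-noise velocities decorrelate at the 3/sqrt(N) level", {
  n <- 100000
  set.seed(1)
  tr <- velocity_trajectory(list(rnorm(n)), dt = 0.1)
  vc <- compute_vacf(tr, max_lag = 5)
  expect_lt(max(abs(vc$values[-1])), 3 / sqrt(n))
})

test_that("VACF input contracts are enforced", {
  pos <- array(0, c(100, 1, 3))
  tr <- trajectory("H", pos, dt = 0.1)
  expect_error(compute_vacf(tr, max_lag = 2), "velocities")
  trv <- velocity_trajectory(list(rnorm(100)), dt = 0.1)
  expect_error(compute_vacf(trv, selection = integer(0), max_lag = 1),
               "selection error")
  expect_error(compute_vacf(trv, max_lag = 8), "half")
})

test_that("a single synthetic mode peaks within one resolution bin", {
  dt <- 0.25; n <- 8192
  tr <- velocity_trajectory(list(mode_velocity(3400, n, dt)), dt = dt)
  sp <- power_spectrum(tr, window = "rect", n_segments = 1)
  bm <- band_maximum(sp, 3000, 3700)
  expect_lt(abs(bm$wavenumber - 3400), sp$resolution)
  expect_true(all(sp$intensity >= 0))
  expect_true(all(diff(sp$wavenumbers) > 0))
})

test_that("Parseval holds exactly for rectangular window, one segment", {
  dt <- 0.25; n <- 4096
  set.seed(8)
  v <- rnorm(n)
  tr <- velocity_trajectory(list(v), labels = "H", dt = dt)
  sp <- power_spectrum(tr, window = "rect", n_segments = 1)
  expect_equal(sum(sp$intensity) * sp$resolution, 1.008 * mean(v^2),
               tolerance = 1e-6)
})

test_that("zero velocities give an identically zero spectrum", {
  tr <- velocity_trajectory(list(rep(0, 512)), dt = 0.25)
  expect_true(all(power_spectrum(tr)$intensity == 0))
})

test_that("disjoint selections add and a two-mode signal shows two bands", {
  dt <- 0.25; n <- 8192
  tr <- velocity_trajectory(list(mode_velocity(3400, n, dt),
                                 mode_velocity(1600, n, dt, phase = 1)),
                            labels = c("H", "H"), dt = dt)
  sall <- power_spectrum(tr, n_segments = 2)
  s1 <- power_spectrum(tr, selection = 1, n_segments = 2)
  s2 <- power_spectrum(tr, selection = 2, n_segments = 2)
  expect_lt(max(abs(sall$intensity - s1$intensity - s2$intensity)), 1e-10)

  # exactly two local maxima above half height
  y <- sall$intensity
  half <- max(y) / 2
  peaks <- which(diff(sign(diff(y))) == -2) + 1
  expect_equal(sum(y[peaks] > half), 2)
  expect_lt(abs(band_maximum(sall, 3000, 3700)$wavenumber - 3400),
            sall$resolution)
  expect_lt(abs(band_maximum(sall, 1400, 1800)$wavenumber - 1600),
            sall$resolution)
})

test_that("band maxima break ties toward lower wavenumber and check ranges", {
  tr <- velocity_trajectory(list(rep(0, 512)), dt = 0.25)
  sp <- power_spectrum(tr)
  bm <- band_maximum(sp, 1000, 2000)
  expect_equal(bm$height, 0)
  expect_equal(bm$wavenumber, min(sp$wavenumbers[sp$wavenumbers >= 1000]))
  expect_error(band_maximum(sp, 1e6, 2e6), "range error")
})

test_that("spectral shifts carry the blueshift/redshift sign convention", {
  dt <- 0.25; n <- 8192
  a <- power_spectrum(velocity_trajectory(list(mode_velocity(3050, n, dt)), dt = dt))
  b <- power_spectrum(velocity_trajectory(list(mode_velocity(3150, n, dt)), dt = dt))
  expect_equal(spectral_shift(a, b, 2800, 3400), 100, tolerance = a$resolution)
  expect_equal(spectral_shift(a, a, 2800, 3400), 0)
  c1 <- power_spectrum(velocity_trajectory(list(mode_velocity(3600, n, dt)), dt = dt))
  c2 <- power_spectrum(velocity_trajectory(list(mode_velocity(3300, n, dt)), dt = dt))
  expect_equal(spectral_shift(c1, c2, 3100, 3800), -300, tolerance = c1$resolution)
})

test_that("hydrogen-bond formation shows as a redshift on synthetic bridges", {
  # free high-frequency stretch vs proton in the softer double well
  s <- sim_settings(dt = 0.25, n_steps = 60000, n_equil = 500, seed = 21,
                    stride = 1, thermostat_time = 5)
  free <- simulate_md(model_potential("harmonic"), s)
  bound <- simulate_md(model_potential("double_well"), s)
  spf <- power_spectrum(free, selection = "H", n_segments = 4)
  spb <- power_spectrum(bound, selection = "H", n_segments = 4)
  expect_lt(spectral_shift(spf, spb, 500, 4000), 0)
})
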