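# Bridge geometry, proton histograms, potentials of mean force and
# transfer statistics.

test_that("distance series reproduce constructed geometries", {
  tr <- bridge_series_trajectory(r_DH = 1.0, r_DA = 2.6)
  ser <- distance_series(tr, bridge_definition(1, 2, 3))
  expect_equal(ser$r_DH, 1.0)
  expect_equal(ser$r_HA, 1.6)
  expect_equal(ser$r_DA, 2.6)
  expect_true(all(ser$r_DA <= ser$r_DH + ser$r_HA + 1e-12))

  # acceptor wrapped across a 5 A cubic boundary: A at (-2.4,0,0); the
  # nearest D...A image is the direct one (2.4 A), the nearest H...A image
  # the wrapped one (1.6 A) - both verified against the brute-force search
  pos <- array(0, c(1, 3, 3))
  pos[1, 2, 1] <- 1.0; pos[1, 3, 1] <- -2.4
  cell <- cell_parameters(5, 5, 5)
  trc <- trajectory(c("O", "H", "O"), pos, cell = cell)
  serc <- distance_series(trc, bridge_definition(1, 2, 3))
  expect_equal(serc$r_DA,
               brute_force_image_distance(c(0, 0, 0), c(-2.4, 0, 0), cell))
  expect_equal(serc$r_DA, 2.4)
  expect_equal(serc$r_HA, 1.6)

  expect_error(bridge_definition(2, 2, 3), "distinct")
  expect_error(distance_series(tr, bridge_definition(1, 2, 9)), "out of range")
})

test_that("pooled bead series stack all replicas", {
  s <- sim_settings(dt = 0.25, n_steps = 400, stride = 4, seed = 5)
  bt <- simulate_pimd(model_potential("double_well"), s, path_settings(4))
  ser <- distance_series(bt, bridge_definition(1, 2, 3))
  expect_equal(nrow(ser), 4 * dim(bt$replicas[[1]]$positions)[1])
})

test_that("2D proton histograms are normalised densities", {
  ser <- series_from_xi(rep(-0.6, 50))
  h <- proton_histogram2d(ser, bin_width = 0.02)
  expect_equal(sum(h$density) * 0.02^2, 1, tolerance = 1e-9)
  expect_equal(max(h$density), 1 / 0.02^2)     # delta distribution: one bin

  set.seed(6)
  n <- 100000
  df <- data.frame(time = seq_len(n), r_DH = rnorm(n, 1.0, 0.05),
                   r_HA = rnorm(n, 1.6, 0.05))
  df$r_DA <- df$r_DH + df$r_HA
  class(df) <- c("hb_geometry", "data.frame")
  h2 <- proton_histogram2d(df, bin_width = 0.02)
  expect_equal(sum(h2$density) * 0.02^2, 1, tolerance = 1e-9)
  # product-Gaussian oracle within 4 sigma (Poisson) per adequately filled bin
  xc <- head(h2$x_edges, -1) + 0.01
  yc <- head(h2$y_edges, -1) + 0.01
  expected <- outer(dnorm(xc, 1.0, 0.05), dnorm(yc, 1.6, 0.05))
  counts_exp <- expected * n * 0.02^2
  check <- counts_exp >= 25
  z <- (h2$counts - counts_exp) / sqrt(counts_exp)
  expect_lt(max(abs(z[check])), 4)
  expect_error(proton_histogram2d(df, bin_width = 0), "range error")
})

test_that("Boltzmann inversion recovers flat and Gaussian free energies", {
  set.seed(9)
  ser <- series_from_xi(runif(200000, -0.5, 0.5))
  pmf <- pmf_from_series(ser, "delta", n_bins = 20, temperature = 297)
  expect_lt(max(pmf$free_energy, na.rm = TRUE), 0.02)  # flat within noise

  sig <- 0.1
  serg <- series_from_xi(rnorm(300000, 0, sig))
  pg <- pmf_from_series(serg, "delta", n_bins = 40, temperature = 297)
  ok <- !is.na(pg$free_energy) & pg$counts > 200
  fit <- lm(pg$free_energy[ok] ~ I(pg$center[ok]^2))
  curv <- 2 * coef(fit)[2]                    # A = a xi^2 -> A'' = 2a
  expect_equal(unname(curv), kB * 297 / sig^2, tolerance = 0.05)
  expect_error(pmf_from_series(series_from_xi(rep(0.1, 50)), "delta"),
               "data error")
})

test_that("PMF equals -kT log of the marginalised 2D histogram", {
  set.seed(10)
  ser <- series_from_xi(rnorm(20000, 0.1, 0.12))
  h <- proton_histogram2d(ser, bin_width = 0.02)
  pmf <- pmf_from_series(ser, "r_HA", breaks = h$y_edges, temperature = 297)
  marg <- colSums(h$density) * 0.02           # 1D density over r_HA
  a_marg <- -kB * 297 * log(marg)
  a_marg <- a_marg - min(a_marg[marg > 0])
  ok <- marg > 0
  expect_lt(max(abs(a_marg[ok] - pmf$free_energy[ok])), 1e-9)
})

test_that("minima and barrier extraction handles constructed profiles", {
  centers <- seq(-1, 1, length.out = 21)
  vals <- (centers^2 - 0.5^2)^2 * 10          # wells at +-0.5, barrier 0.625
  prof <- data.frame(center = centers, free_energy = vals - min(vals),
                     counts = rep(10, 21))
  attr(prof, "temperature") <- 297
  class(prof) <- c("pmf_profile", "data.frame")
  lb <- locate_minima_barrier(prof)
  expect_equal(sort(lb$minima$position[order(lb$minima$value)[1:2]]),
               c(-0.5, 0.5))
  expect_equal(lb$barrier, 10 * 0.0625, tolerance = 1e-9)
  expect_equal(lb$saddle, 0)

  mono <- prof
  mono$free_energy <- seq(0, 2, length.out = 21)
  lbm <- locate_minima_barrier(mono)
  expect_equal(nrow(lbm$minima), 1)
  expect_true(is.na(lbm$barrier))
})

test_that("classical MD on the double well recovers the generator barrier", {
  m <- model_potential("double_well", V0 = 3.1)
  s <- sim_settings(dt = 0.5, n_steps = 1500000, n_equil = 2000, seed = 9,
                    stride = 3, thermostat_time = 10)
  ser <- distance_series(simulate_md(m, s), bridge_definition(1, 2, 3))
  pmf <- pmf_from_series(ser, "delta", n_bins = 60, temperature = 297)
  lb <- locate_minima_barrier(pmf)
  expect_lt(abs(lb$barrier - 3.1), 0.3)
  expect_equal(sort(abs(lb$minima$position[order(lb$minima$value)[1:2]])),
               c(0.7, 0.7), tolerance = 0.1)  # delta = 2 x at x = +-a0
})

test_that("quantum sampling lowers the proton-transfer barrier", {
  m <- model_potential("double_well", V0 = 3.1)
  s <- sim_settings(dt = 0.25, n_steps = 400000, n_equil = 2000, seed = 14,
                    stride = 10, thermostat_time = 5)
  serq <- distance_series(simulate_pimd(m, s, path_settings(8)),
                          bridge_definition(1, 2, 3))
  scl <- sim_settings(dt = 0.5, n_steps = 1500000, n_equil = 2000, seed = 15,
                      stride = 3, thermostat_time = 10)
  serc <- distance_series(simulate_md(m, scl), bridge_definition(1, 2, 3))
  bq <- locate_minima_barrier(pmf_from_series(serq, "delta", n_bins = 50))$barrier
  bc <- locate_minima_barrier(pmf_from_series(serc, "delta", n_bins = 50))$barrier
  expect_lt(bq, bc)
})

test_that("transfer detection counts confirmed crossings only", {
  ev <- detect_transfers(series_from_xi(seq(-0.5, 0.5, length.out = 100)), 0.1)
  expect_equal(ev$n_events, 1)

  ev2 <- detect_transfers(series_from_xi(rep(-0.3, 50)), 0.1)
  expect_equal(ev2$n_events, 0)
  expect_equal(ev2$residence_donor, 1)

  # rapid flicker inside the dead band is suppressed
  set.seed(11)
  flick <- series_from_xi(c(-0.3, runif(200, -0.09, 0.09), -0.3))
  ev3 <- detect_transfers(flick, 0.1)
  expect_equal(ev3$n_events, 0)

  # random walks agree with the literal reference state machine
  for (rep in 1:20) {
    xi <- cumsum(rnorm(500, 0, 0.08))
    ref <- reference_transfer_machine(xi, 0.1)
    got <- detect_transfers(series_from_xi(xi), 0.1)
    expect_equal(got$n_events, ref$n_events)
    expect_equal(got$residence_donor, ref$residence_donor)
    expect_equal(got$residence_donor + got$residence_acceptor, 1)
  }
  expect_equal(detect_transfers(series_from_xi(numeric(0)))$n_events, 0)
})
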