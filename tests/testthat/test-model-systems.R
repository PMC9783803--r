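# Analytic potentials, classical MD, staging PIMD and the exact quantum
# references that validate them.

test_that("analytic potentials match their defining values and gradients", {
  h <- model_potential("harmonic")
  ev <- evaluate_potential(h, 0)
  expect_equal(ev$energy, 0)
  expect_equal(ev$fx, 0)

  dw <- model_potential("double_well", V0 = 3.1, a0 = 0.35)
  expect_equal(evaluate_potential(dw, c(-0.35, 0.35))$energy, c(0, 0))
  expect_equal(evaluate_potential(dw, 0)$energy, 3.1)

  # coupled bridge: analytic force vs 5-point central differences
  cb <- model_potential("coupled_bridge")
  pts <- expand.grid(x = c(-0.4, -0.1, 0, 0.2, 0.45), R = c(2.45, 2.6, 2.8))
  d <- 1e-4
  for (i in seq_len(nrow(pts))) {
    x <- pts$x[i]; R <- pts$R[i]
    ev <- evaluate_potential(cb, x, R)
    e <- function(xx, RR) evaluate_potential(cb, xx, RR)$energy
    gx <- (e(x - 2*d, R) - 8*e(x - d, R) + 8*e(x + d, R) - e(x + 2*d, R)) / (12 * d)
    gR <- (e(x, R - 2*d) - 8*e(x, R - d) + 8*e(x, R + d) - e(x, R + 2*d)) / (12 * d)
    expect_equal(ev$fx, -gx, tolerance = 1e-6)
    expect_equal(ev$fR, -gR, tolerance = 1e-6)
  }
  expect_error(model_potential("double_well", a0 = 1.5, R0 = 2.6), "R0")
})

test_that("NVE velocity Verlet conserves energy (windowed-mean drift < 1e-4)", {
  s <- sim_settings(dt = 0.1, n_steps = 100000, thermostat = "none", seed = 2)
  for (kind in c("harmonic", "double_well")) {
    d <- attr(simulate_md(model_potential(kind), s), "dynamics")
    E <- d$epot + d$ekin
    drift <- abs(mean(tail(E, 10000)) - mean(head(E, 10000))) / abs(E[1])
    expect_lt(drift, 1e-4)
  }
})

test_that("Nose-Hoover chains give equipartition per degree of freedom", {
  s <- sim_settings(dt = 0.25, n_steps = 800000, n_equil = 2000, seed = 3,
                    stride = 10, thermostat_time = 5)
  d <- attr(simulate_md(model_potential("coupled_bridge"), s), "dynamics")
  kT2 <- 0.5 * kB * 297
  for (ke in list(0.5 * 1.008 * massfac * d$vx^2,
                  0.5 * 15.999 / 2 * massfac * d$vR^2)) {
    se <- blocked_se(ke)
    expect_lt(abs(mean(ke) - kT2), 3 * se)
  }
})

test_that("degenerate production segment and divergence are reported", {
  expect_error(sim_settings(n_steps = 100, n_equil = 100), "n_equil")
  # a huge time step on a stiff well blows up and names the step
  s <- sim_settings(dt = 50, n_steps = 1000, thermostat = "none", seed = 1)
  expect_error(simulate_md(model_potential("harmonic"), s),
               "integration failure.*step")
})

test_that("identical seeds give bit-identical trajectories", {
  s <- sim_settings(dt = 0.25, n_steps = 2000, seed = 77)
  t1 <- simulate_md(model_potential("double_well"), s)
  t2 <- simulate_md(model_potential("double_well"), s)
  expect_identical(t1$positions, t2$positions)
  b1 <- simulate_pimd(model_potential("double_well"), s, path_settings(4))
  b2 <- simulate_pimd(model_potential("double_well"), s, path_settings(4))
  expect_identical(attr(b1, "dynamics")$beads, attr(b2, "dynamics")$beads)
})

test_that("staging transform has the stated images and exact round trip", {
  expect_equal(staging_transform(rep(1.3, 6)), c(1.3, rep(0, 5)))
  expect_equal(staging_transform(0.7), 0.7)       # P = 1 identity
  expect_equal(inverse_staging(0.7), 0.7)
  set.seed(4)
  for (i in 1:20) {
    x <- rnorm(8)
    expect_equal(inverse_staging(staging_transform(x)), x, tolerance = 1e-12)
  }
  u <- matrix(rnorm(16), 8, 2)
  expect_equal(inverse_staging(staging_transform(u)), u, tolerance = 1e-12)
})

ho <- model_potential("harmonic")      # 3400 cm^-1 proton stretch
omega <- sqrt(ho$k_harm / (1.008 * massfac))

pimd_run <- function(P, n_steps = 300000, seed = 11) {
  s <- sim_settings(dt = 0.1, n_steps = n_steps, n_equil = 2000, seed = seed,
                    stride = 10, thermostat_time = 5)
  simulate_pimd(ho, s, path_settings(P))
}

test_that("P = 1 path-integral sampling reproduces the classical closed forms", {
  bt <- pimd_run(1)
  x2s <- attr(bt, "dynamics")$beads[, 1]^2
  expect_lt(abs(mean(x2s) - kB * 297 / (1.008 * massfac * omega^2)),
            3 * blocked_se(x2s))
  ee <- energy_estimators(bt, ho)
  # both estimators reduce to the classical <KE + PE> = kB T
  expect_lt(abs(ee$primitive - kB * 297), 3 * ee$primitive_se)
  expect_lt(abs(ee$virial - kB * 297), 3 * ee$virial_se)
  expect_equal(ee$primitive, ee$virial, tolerance = 1e-9)
})

test_that("P-bead sampling matches the exact finite-P laws and converges
          monotonically toward the coth laws as P doubles", {
  x2_coth <- ho_x2_quantum(1.008, omega, 297)
  e_coth <- ho_energy_quantum(1.008, omega, 297)
  prev_x2 <- 0
  for (P in c(8, 16, 32)) {
    bt <- pimd_run(P)
    beads <- attr(bt, "dynamics")$beads
    x2s <- rowMeans(beads^2)
    x2_exact <- ho_x2_finiteP(1.008, omega, 297, P)
    expect_lt(abs(mean(x2s) - x2_exact), 3 * blocked_se(x2s))
    ee <- energy_estimators(bt, ho)
    e_exact <- ho_energy_finiteP(1.008, omega, 297, P)
    expect_lt(abs(ee$virial - e_exact), 3 * ee$virial_se)
    expect_lt(abs(ee$primitive - e_exact), 3 * ee$primitive_se)
    # primitive and centroid-virial agree within combined errors
    expect_lt(abs(ee$primitive - ee$virial),
              3 * sqrt(ee$primitive_se^2 + ee$virial_se^2))
    # finite-P expectations approach the continuum coth laws from below
    expect_gt(x2_exact, prev_x2)
    expect_lt(x2_exact, x2_coth)
    expect_lt(e_exact, e_coth)
    prev_x2 <- x2_exact
  }
})

test_that("quantum effects raise the barrier-top density of the double well", {
  dw <- model_potential("double_well", V0 = 3.1)
  s <- sim_settings(dt = 0.25, n_steps = 300000, n_equil = 2000, seed = 7,
                    stride = 10, thermostat_time = 5)
  mid <- seq(-0.1, 0.1, by = 0.05)
  d8 <- bead_position_density(simulate_pimd(dw, s, path_settings(8)), mid)
  d1 <- bead_position_density(simulate_pimd(dw, s, path_settings(1)), mid)
  expect_gt(mean(d8$density), mean(d1$density))
})

test_that("grid-diagonalisation density matches closed forms and symmetry", {
  g <- seq(-0.6, 0.6, length.out = 601)
  rd <- reference_quantum_density(ho, 297, g)
  s2 <- ho_x2_quantum(1.008, omega, 297)
  gauss <- exp(-g^2 / (2 * s2)) / sqrt(2 * pi * s2)
  expect_lt(max(abs(rd$density - gauss)) / max(gauss), 1e-4)
  expect_equal(sum(rd$density) * (g[2] - g[1]), 1, tolerance = 1e-9)

  dw <- model_potential("double_well", V0 = 3)
  g2 <- seq(-1, 1, length.out = 801)
  rd2 <- reference_quantum_density(dw, 297, g2)
  expect_lt(max(abs(rd2$density - rev(rd2$density))), 1e-10)

  # a too-coarse grid is refused rather than silently wrong
  expect_error(reference_quantum_density(ho, 297, seq(-0.6, 0.6, length.out = 40)),
               "resolution error")
})
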