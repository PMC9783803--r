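# Espinosa bond energies, covalency classification and SAPT accounting on
# the tabulated descriptors of the benzamide (D) and benzoic-acid (E) dimers.

qtaim_path <- system.file("extdata", "qtaim_bcp_dimer_descriptors.csv",
                          package = "hbdyn")
sapt_path <- system.file("extdata", "sapt_dimer_components.csv",
                         package = "hbdyn")

test_that("Espinosa energies reproduce the tabulated bond energies", {
  df <- read_qtaim_table(qtaim_path)
  e <- espinosa_energy(df)
  hb <- !is.na(df$E1)
  expect_equal(sum(hb), 5)
  # 0.5% relative: the printed V_BCP values are rounded to 4 decimals
  expect_lt(max(abs(e[hb] - df$E1[hb]) / df$E1[hb]), 0.005)
  expect_true(all(is.na(e[!hb])))               # covalent rows: no Espinosa value

  cp <- critical_point("OD-H...OA", 0.0384, -0.0381, 0.1349, -0.0022)
  expect_equal(espinosa_energy(cp), 0.5 * 0.0381 * 627.5095)
  expect_equal(espinosa_energy(cp, signed = TRUE), -0.5 * 0.0381 * 627.5095)
  expect_equal(espinosa_energy(critical_point("x", 0.01, 0, 0.1)), 0)
  expect_true(is.na(espinosa_energy(
    critical_point("ND-H", 0.4652, -1.0418, -3.5875, -0.9694))))
  expect_error(espinosa_energy(critical_point("r", 0.01, -0.01, 0.05,
                                              cp_type = "RCP")), "type error")
  # exact linearity in V_BCP
  v <- -c(0.01, 0.02, 0.04)
  es <- vapply(v, function(vi)
    espinosa_energy(critical_point("x", 0.02, vi, 0.1)), numeric(1))
  expect_equal(es / abs(v), rep(0.5 * 627.5095, 3))
})

test_that("bond-energy orderings match the strengthening on optimisation", {
  df <- read_qtaim_table(qtaim_path)
  e1 <- function(sys, lab) df$E1[df$system == sys & df$label == lab]
  # O-H...O stronger than N-H...O within each structure pair
  expect_gt(e1("E1", "OD-H...OA"), e1("D1", "ND-H...OA"))
  expect_gt(e1("E2", "OD-H...OA"), e1("D2", "ND-H...OA"))
  # optimisation strengthens both hydrogen bonds
  expect_gt(e1("D2", "ND-H...OA"), e1("D1", "ND-H...OA"))
  expect_gt(e1("E2", "OD-H...OA"), e1("E1", "OD-H...OA"))
})

test_that("sign-based classification assigns the expected classes", {
  expect_equal(classify_interaction(
    critical_point("ND-H...OA", 0.0183, -0.0124, 0.0790, 0.0037)),
    "closed_shell_electrostatic")
  expect_equal(classify_interaction(
    critical_point("OD-H...OA", 0.0384, -0.0381, 0.1349, -0.0022)),
    "closed_shell_partially_covalent")
  expect_equal(classify_interaction(
    critical_point("ND-H", 0.4652, -1.0418, -3.5875, -0.9694)),
    "shared_shell_covalent")
  expect_message(cls <- classify_interaction(
    critical_point("x", 0.01, -0.01, 0.05, 1e-8)), "zero")
  expect_equal(cls, "closed_shell_electrostatic")
  expect_error(classify_interaction(critical_point("x", 0.01, -0.01, 0.05)),
               "data error")

  # every tabulated row matches the verbal assignment pattern
  df <- read_qtaim_table(qtaim_path)
  cls <- vapply(seq_len(nrow(df)), function(i)
    classify_interaction(critical_point(df$label[i], df$rho[i], df$V_BCP[i],
                                        df$laplacian[i], df$H_BCP[i])), "")
  expect_equal(cls[df$system == "D1" & df$label == "F...N"],
               "closed_shell_electrostatic")
  expect_true(all(cls[df$laplacian < 0] == "shared_shell_covalent"))
  expect_equal(cls[df$system == "E2" & df$label == "OD-H...OA"],
               "closed_shell_partially_covalent")
})

test_that("SAPT totals are the exact component sums", {
  comps <- as_sapt_components(read_sapt_table(sapt_path))
  sums <- vapply(comps, sapt_total, numeric(1))
  expect_equal(sums[3], -24.472 + 27.813 - 10.886 - 8.037)   # = -15.582
  expect_equal(sums[1], -12.147)
  expect_equal(sapt_total(sapt_components(0, 0, 0, 0)), 0)
  expect_error(sapt_components(1, -0.5, 0, 0), "exchange")
})

test_that("SAPT audits flag discrepancies and the steric balance sign", {
  comps <- as_sapt_components(read_sapt_table(sapt_path))
  names(comps) <- vapply(comps, `[[`, "", "label")
  ae1 <- audit_sapt(comps[["E1"]], tol = 0.01)
  expect_true(ae1$pass)
  expect_true(ae1$steric_repulsive)
  expect_equal(ae1$steric_balance, -27.448 + 33.520)  # +6.072, net repulsive

  ad1 <- audit_sapt(comps[["D1"]], tol = 0.005)
  expect_equal(ad1$discrepancy, -0.001, tolerance = 1e-9)
  expect_true(ad1$pass)                       # |0.001| <= 0.005
  expect_false(audit_sapt(comps[["D1"]], tol = 5e-4)$pass)

  fab <- sapt_components(-10, 8, -2, -1, E_total_reported = -4)
  bad <- audit_sapt(fab, tol = 0.01)
  expect_false(bad$pass)
  expect_equal(bad$discrepancy, -1)
  expect_error(audit_sapt(sapt_components(1, 1, 1, 1)), "data error")
})

test_that("descriptor tables parse with Unicode minus and strict headers", {
  df <- read_descriptor_tables(qtaim_path)
  expect_equal(nrow(df), 13)
  expect_equal(sum(df$cp_type == "BCP"), 13)
  ds <- read_descriptor_tables(sapt_path)
  expect_equal(nrow(ds), 4)

  p <- tempfile(fileext = ".csv")
  writeLines(c("label,rho,V_BCP,laplacian,H_BCP",
               "X,0.01,−0.0381,0.1,0.001"), p)
  expect_equal(read_qtaim_table(p)$V_BCP, -0.0381)

  writeLines(c("label,rho,laplacian,H_BCP", "X,0.01,0.1,0.001"), p)
  expect_error(read_qtaim_table(p), "V_BCP")
  writeLines(c("label,rho,V_BCP,laplacian,H_BCP",
               "X,0.01,oops,0.1,0.001"), p)
  expect_error(read_qtaim_table(p), "row 1")
  writeLines(c("a,b", "1,2"), p)
  expect_error(read_descriptor_tables(p), "format error")
})
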