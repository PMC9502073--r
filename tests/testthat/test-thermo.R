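test_that("proton gas-phase Gibbs energy matches the literature value and the closed form", {
  expect_equal(proton_gas_gibbs(298.15), -6.28, tolerance = 0.01 / 6.28)
  expect_equal(proton_gas_gibbs(298.15) * 4.184, -26.28,
               tolerance = 0.05 / 26.28)
  # less negative at lower temperature
  expect_gt(proton_gas_gibbs(100), proton_gas_gibbs(298.15))
  for (T in c(100, 150, 298.15, 400, 500))
    expect_equal(proton_gas_gibbs(T), sackur_tetrode_oracle(T),
                 tolerance = 1e-6 / abs(sackur_tetrode_oracle(T)))
  expect_error(proton_gas_gibbs(0), "temperature")
  expect_error(proton_gas_gibbs(-5), "temperature")
})

test_that("standard-state correction reproduces 1.89 kcal/mol and its closed form", {
  expect_equal(standard_state_correction(298.15), 1.89,
               tolerance = 0.01 / 1.89)
  for (T in c(100, 298.15, 310, 500))
    expect_equal(standard_state_correction(T), std_state_oracle(T),
                 tolerance = 1e-6)
  expect_error(standard_state_correction(0), "temperature")
})

test_that("proton Gibbs energy assembly and its inverse round-trip", {
  expect_equal(assemble_proton_gibbs(-6.28, -252.9, 1.89), -257.3,
               tolerance = 0.0101 / 257.3)
  expect_equal(solvation_from_total(-258.8, -6.28, 1.89), -254.4,
               tolerance = 0.05 / 254.4)
  expect_identical(assemble_proton_gibbs(0, 0, 0), 0)
  set.seed(11)
  for (i in 1:25) {
    g <- stats::rnorm(1, -6, 2); s <- stats::rnorm(1, -250, 20)
    ss <- stats::rnorm(1, 2, 1)
    tot <- assemble_proton_gibbs(g, s, ss)
    expect_equal(solvation_from_total(tot, g, ss), s, tolerance = 1e-10)
  }
  expect_error(assemble_proton_gibbs(NA, 0, 0), "finite")
})

test_that("reduced basicity sums the four species energies", {
  rec <- function(ggB, dsB, ggBH, dsBH, id = "x")
    base_record(id, "P", "demo",
                species_thermo(ggB, dsB, "B"),
                species_thermo(ggBH, dsBH, "BH+"))
  expect_equal(reduced_basicity(rec(0, 0, 0, 0)), 0)
  expect_equal(reduced_basicity(rec(17.3, 0, 0, 0)), 17.3)
  expect_equal(reduced_basicity(rec(-7e5, -5, -700290, -45)), 330,
               tolerance = 1e-9)
  # uniform shifts of the gas-phase pair or the solvation pair cancel
  base <- reduced_basicity(rec(-700000, -5, -700290, -45))
  expect_equal(reduced_basicity(rec(-700000 + 123.4, -5, -700290 + 123.4, -45)),
               base, tolerance = 1e-9)
  expect_equal(reduced_basicity(rec(-700000, -5 - 9.9, -700290, -45 - 9.9)),
               base, tolerance = 1e-9)
  # a missing energy names the offending record
  r <- rec(-700000, -5, -700290, -45, id = "bad-one")
  r$neutral$g_gas <- NA_real_
  expect_error(reduced_basicity(r), "bad-one")
})

test_that("reduced basicity works columnwise on an energy table", {
  tab <- data.frame(g_gas_B = c(-7e5, 0), dg_solv_B = c(-5, 0),
                    g_gas_BH = c(-700290, 0), dg_solv_BH = c(-45, 0))
  expect_equal(reduced_basicity(tab), c(330, 0), tolerance = 1e-9)
  expect_error(reduced_basicity(tab[, -1]), "g_gas_B")
})

test_that("gas-phase basicity is the three-term protonation Gibbs energy", {
  rec <- function(ggB, ggBH)
    base_record("g", "P", "demo", species_thermo(ggB, -5),
                species_thermo(ggBH, -45))
  expect_equal(gas_basicity(rec(-1234.5, -1234.5)), proton_gas_gibbs(298.15))
  expect_equal(gas_basicity(rec(-5e5, -500242.28)), 236, tolerance = 0.02 / 236)
  gb0 <- gas_basicity(rec(-5e5, -500242.28))
  expect_equal(gas_basicity(rec(-5e5, -500242.28 + 0.77)), gb0 - 0.77,
               tolerance = 1e-9)
})

test_that("thermodynamic-cycle pKa behaves as (dG' + G_sol(H+))/ln(10)RT", {
  expect_equal(pka_from_reduced_basicity(258.8, -258.8), 0)
  expect_equal(pka_from_reduced_basicity(300, -258.8), 30.19,
               tolerance = 0.05 / 30.19)
  p0 <- pka_from_reduced_basicity(290, -258.8)
  expect_equal(pka_from_reduced_basicity(290 + ln10RT(), -258.8), p0 + 1,
               tolerance = 1e-12)
  # exact integer pKa recovery through the assembled literature chain
  g <- assemble_proton_gibbs(-6.28, -252.9, 1.89)
  for (k in c(0, 1, -1, 10, -10, 30)) {
    dg <- ln10RT() * k - g
    expect_equal(pka_from_reduced_basicity(dg, g), k, tolerance = 1e-12)
  }
})

test_that("ideal slope is the reciprocal of ln(10)RT", {
  expect_equal(ideal_slope(298.15), 0.733, tolerance = 0.001 / 0.733)
  expect_equal(ideal_slope(298.15) * ln10RT(298.15), 1)
  expect_equal(ideal_slope(2 * 317), ideal_slope(317) / 2, tolerance = 1e-12)
  expect_error(ideal_slope(-1), "temperature")
})

test_that("thermo_constants chain is internally consistent", {
  tc <- thermo_constants()
  expect_equal(tc$ln10RT, log(10) * tc$R * tc$T, tolerance = 1e-12)
  expect_equal(tc$g_gas_proton, proton_gas_gibbs(tc$T), tolerance = 1e-12)
  expect_equal(tc$ss_correction, standard_state_correction(tc$T),
               tolerance = 1e-12)
  expect_equal(tc$g_lit,
               tc$g_gas_proton + tc$dgs_proton_lit + tc$ss_correction)
  expect_output(print(tc), "0.733")
})

test_that("species and record constructors validate and convert units", {
  sp <- species_thermo(-1.5, -0.01, unit_gas = "hartree",
                       unit_solv = "hartree")
  expect_equal(sp$g_gas, -1.5 * KCAL_PER_HARTREE)
  expect_equal(sp$dg_solv, -0.01 * KCAL_PER_HARTREE)
  expect_error(species_thermo(Inf, 0), "finite")
  expect_error(
    base_record("r1", "S", "m", species_thermo(0, 0), species_thermo(0, 0)),
    "\\{N, P, C\\}")
  expect_warning(
    base_record("r2", "N", "m", species_thermo(0, -5), species_thermo(0, 3)),
    "positive solvation")
})
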