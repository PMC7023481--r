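sol <- ibuprofen_solubility_profile()
gi_grid <- c(0, 0.25, 0.5, 0.75, 1, 1.5, 2, 2.5, 3, 4, 5, 6, 7)
full_grid <- sort(unique(c(gi_grid, 8, 12, 28)))

test_that("pH series interpolation is piecewise linear with flat tails", {
  ser <- data.frame(time_h = c(1, 2, 3), pH = c(5.0, 7.0, 6.5))
  expect_equal(pH_at(ser, 2), 7.0)
  expect_equal(pH_at(ser, 1.5), 6.0)
  expect_equal(pH_at(ser, 10), 6.5)
  expect_equal(pH_at(ser, 0), 5.0)
  expect_equal(pH_at(data.frame(time_h = 1, pH = 6.1), c(0, 5)), c(6.1, 6.1))
  expect_error(pH_at(data.frame(time_h = numeric(0), pH = numeric(0)), 1),
               "empty")
})

test_that("dissolution rate follows the bilinear saturation-gap law", {
  expect_equal(dissolution_rate(0, 50, 6.5, 1.5e-3, sol), 0)
  cs <- solubility_at_pH(sol, 6.5)
  expect_equal(dissolution_rate(1e5, cs, 6.5, 1.5e-3, sol), 0)
  # driving force clamped: no re-precipitation above saturation
  expect_equal(dissolution_rate(1e5, cs * 2, 6.5, 1.5e-3, sol), 0)
  # units: mL/(ug h) x ug x ug/mL = ug/h
  flat <- acid_solubility_profile(100, 4.54, cap = 1)
  expect_equal(dissolution_rate(1e5, 0, 6.5, 0.0015, flat),
               0.0015 * 1e5 * 100)
  expect_error(dissolution_rate(-1, 0, 6.5, 1e-3, sol), ">= 0")
})

test_that("mass balance closes to 1e-6 under both variants", {
  phys <- make_ref_subject(wiggly = TRUE)
  tr <- simulate_gis(ref_params(), phys, 8e5, full_grid, solubility = sol)
  expect_lt(max(gis_mass_balance_error(tr)), 1e-6)
  basic <- gis_parameters(0.5, 0.47, 0.081, Kd_simple = 1.2)
  tr2 <- simulate_gis(basic, phys, 8e5, full_grid)
  expect_lt(max(gis_mass_balance_error(tr2)), 1e-6)
})

test_that("the phase-III event empties the stomach exactly at TMMC", {
  phys <- make_ref_subject(tmmc = 2.04)
  pars <- gis_parameters(0.5, 0.47, 0.081, K_Diss = 1.52e-3)
  grid <- sort(unique(c(full_grid, 2.04 - 1e-6, 2.04)))
  tr <- simulate_gis(pars, phys, 8e5, grid, solubility = sol)
  pre <- tr$M_stomach_solid[tr$time_h == 2.04 - 1e-6]
  expect_equal(pre, 8e5 * exp(-0.5 * (2.04 - 1e-6)), tolerance = 1e-6)
  expect_equal(tr$M_stomach_solid[tr$time_h == 2.04], 0)
  # the bolus lands in the duodenal solid pool
  post_duo <- tr$M_duodenum_solid[tr$time_h == 2.04]
  pre_duo <- tr$M_duodenum_solid[tr$time_h == 2.04 - 1e-6]
  expect_equal(post_duo, pre_duo + pre, tolerance = 1e-6)
})

test_that("zero dissolution keeps plasma empty and mass in solid pools", {
  phys <- make_ref_subject()
  tr <- simulate_gis(gis_parameters(0.18, 0.47, 0.081, K_Diss = 0),
                     phys, 8e5, full_grid, solubility = sol)
  expect_true(all(tr$C_plasma == 0))
  solid <- tr$M_stomach_solid + tr$M_duodenum_solid + tr$M_jejunum_solid +
    tr$cumulative_distal_transit
  expect_equal(solid, rep(8e5, nrow(tr)), tolerance = 1e-6)
  tr2 <- simulate_gis(gis_parameters(0.18, 0.47, 0.081, Kd_simple = 0),
                      phys, 8e5, full_grid)
  expect_true(all(tr2$C_plasma == 0))
})

test_that("far-from-saturation gisplus collapses to the basic model", {
  # constant, enormous solubility: driving force ~ Cs everywhere, so
  # K_Diss * Cs plays the role of the basic first-order rate
  big <- acid_solubility_profile(1e6, 7, cap = 1)
  phys <- make_ref_subject(tmmc = 99)  # event beyond the horizon
  kd <- 2e-6
  plus <- simulate_gis(gis_parameters(0.18, 0.47, 0.081, K_Diss = kd),
                       phys, 8e5, full_grid, solubility = big)
  basic <- simulate_gis(gis_parameters(0.18, 0.47, 0.081,
                                       Kd_simple = kd * 1e6),
                        phys, 8e5, full_grid)
  rel <- abs(plus$C_plasma - basic$C_plasma) / max(basic$C_plasma)
  expect_lt(max(rel), 0.01)
})

test_that("gastric fraction remaining matches closed forms", {
  phys <- make_ref_subject(tmmc = 2.04)
  pars <- gis_parameters(1, 0.47, 0.081, K_Diss = 1.52e-3)
  grid <- c(0, log(2), 1, 2.04, 3)
  gf_plus <- gastric_fraction_remaining(pars, phys, grid)
  expect_equal(gf_plus$fraction_remaining[1], 1)
  expect_equal(gf_plus$fraction_remaining[grid == log(2)], 0.5)
  expect_equal(gf_plus$fraction_remaining[grid >= 2.04], c(0, 0))
  expect_true(all(diff(gf_plus$fraction_remaining) <= 0))
  gf <- gastric_fraction_remaining(pars, phys, grid, variant = "gis")
  expect_equal(gf$fraction_remaining, exp(-grid))
})

test_that("states stay non-negative and mass balanced over random draws", {
  set.seed(123)
  phys_base <- make_ref_subject(wiggly = TRUE)
  for (i in 1:200) {
    pars <- gis_parameters(
      Kempt = runif(1, 0.01, 4), K_TD = runif(1, 0.05, 10),
      K_TJ = runif(1, 0.001, 1.2), K_Diss = 10^runif(1, -4.5, -0.5)
    )
    phys <- phys_base
    phys$TMMC <- runif(1, 0.2, 6)
    tr <- simulate_gis(pars, phys, 8e5, gi_grid, solubility = sol)
    expect_true(all(as.matrix(tr[, 2:9]) >= 0))
    expect_lt(max(gis_mass_balance_error(tr)), 1e-6)
  }
})

test_that("adaptive solution agrees with a fixed-step RK4 oracle to 0.1%", {
  phys <- make_ref_subject(tmmc = 2.04, wiggly = TRUE)
  pars <- ref_params()
  grid <- c(1, 2, 2.5, 4, 7)
  tr <- simulate_gis(pars, phys, 8e5, c(0, grid), solubility = sol)
  ora <- oracle_gis_rk4(pars, phys, 8e5, grid, sol, dt = 1e-3)
  for (st in colnames(ora)) {
    got <- tr[[st]][match(grid, tr$time_h)]
    scale <- max(abs(ora[, st]), 8e5 * 1e-6)
    expect_lt(max(abs(got - ora[, st])) / scale, 1e-3)
  }
})

test_that("earlier phase-III onset never lowers plasma Cmax", {
  pars <- ref_params()
  cmax <- vapply(c(0.5, 1, 2, 3), function(tm) {
    phys <- make_ref_subject(tmmc = tm)
    max(simulate_gis(pars, phys, 8e5, full_grid, solubility = sol)$C_plasma)
  }, 0)
  expect_true(all(diff(cmax) <= 1e-9))
})

test_that("halving the dissolution coefficient never increases absorption", {
  phys <- make_ref_subject(wiggly = TRUE)
  absorbed <- function(kd) {
    tr <- simulate_gis(gis_parameters(0.18, 0.47, 0.081, K_Diss = kd),
                       phys, 8e5, full_grid, solubility = sol)
    tr$M_plasma + tr$cumulative_eliminated
  }
  for (kd in c(1.52e-3, 1e-2, 1e-1)) {
    expect_true(all(absorbed(kd / 2) <= absorbed(kd) + 1e-6 * 8e5))
  }
})

test_that("invalid inputs and variant mismatches are rejected", {
  phys <- make_ref_subject()
  expect_error(gis_parameters(-0.1, 0.4, 0.08, K_Diss = 1e-3), ">= 0")
  expect_error(gis_parameters(0.1, 0.4, 0.08), "exactly one")
  expect_error(gis_parameters(0.1, 0.4, 0.08, K_Diss = 1e-3,
                              Kd_simple = 1), "exactly one")
  pars <- ref_params()
  expect_error(simulate_gis(pars, phys, -5, gi_grid, solubility = sol),
               "> 0")
  expect_error(simulate_gis(pars, phys, 8e5, c(1, 2), solubility = sol),
               "start at 0")
  expect_error(simulate_gis(pars, phys, 8e5, gi_grid, variant = "gis"),
               "variant")
  expect_error(simulate_gis(pars, phys, 8e5, gi_grid), "solubility")
})
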