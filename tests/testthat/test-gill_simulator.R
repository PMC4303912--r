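cmp <- gill_compounds()

test_that("paracellular permeability reproduces the TER tiers and is monotone", {
  expect_equal(paracellular_permeability(0), 3.6e-6)
  expect_equal(paracellular_permeability(18.1), 0.1e-6)
  expect_equal(paracellular_permeability(0.2), 1.1e-6)
  expect_equal(paracellular_permeability(0.6), 1.1e-6)
  expect_equal(paracellular_permeability(1.0), 1.1e-6)
  expect_equal(paracellular_permeability(2.0), 0.1e-6)
  ters <- seq(0, 20, by = 0.05)
  p <- paracellular_permeability(ters)
  expect_true(all(diff(p) <= 1e-20))
  expect_error(paracellular_permeability(-0.1))
})

test_that("flux terms vanish at equilibrium and saturate at high substrate", {
  ins <- insert_config("i", ter = 18.1, apical_medium = "L15")
  passive <- transport_params(p_trans = 1e-5)
  f <- flux_terms(5, 5, ins, passive, cmp$propranolol)
  expect_equal(f$net, 0)
  # carrier-only: J -> jmax * A as S >> km
  carrier <- transport_params(uptake_jmax = 1e-4, uptake_km = 50)
  f_sat <- flux_terms(5e6, 0, ins, carrier, cmp$propranolol)
  expect_equal(f_sat$uptake, 1e-4 * 0.9, tolerance = 1e-4)
  f_half <- flux_terms(50, 0, ins, carrier, cmp$propranolol)
  expect_equal(f_half$uptake, 1e-4 * 0.9 / 2)
})

test_that("passive flux scales with the neutral fraction at the donor pH", {
  # closed-form oracle: with an empty receiver the pH 8 : pH 6 flux ratio for
  # a base is f_n(8)/f_n(6) = (1 + 10^(pKa-6)) / (1 + 10^(pKa-8))
  passive <- transport_params(p_trans = 1e-5)
  j_at_ph <- function(ph) {
    ins <- insert_config("i", ter = 0, apical_medium = "freshwater",
                         apical_ph = ph)
    flux_terms(10, 0, ins, passive, cmp$propranolol)$passive
  }
  expected <- (1 + 10^(9.42 - 6)) / (1 + 10^(9.42 - 8))
  expect_equal(j_at_ph(8) / j_at_ph(6), expected, tolerance = 1e-10)
  expect_equal(expected, 96.39, tolerance = 1e-3)
})

test_that("inhibitors scale only the targeted carrier capacity", {
  ins <- insert_config("i", ter = 18.1, apical_medium = "freshwater")
  pars <- transport_params(
    p_trans = 1e-5, uptake_jmax = 1e-4, uptake_km = 50, asym_bias = 2,
    inhibitor_sensitivity = list(
      blocker = list(target = "uptake", fraction_remaining = 0.25)))
  f0 <- flux_terms(10, 0, ins, pars, cmp$propranolol)
  f1 <- flux_terms(10, 0, ins, pars, cmp$propranolol, inhibitor = "blocker")
  expect_equal(f1$uptake, 0.25 * f0$uptake)
  expect_equal(f1$passive, f0$passive)
  f2 <- flux_terms(10, 0, ins, pars, cmp$propranolol, inhibitor = "unknown")
  expect_equal(f2$uptake, f0$uptake)
})

test_that("zero-parameter simulation only removes aliquots, leaving concentrations flat", {
  # all carrier/transcellular pathways off; equal concentrations keep the
  # TER-driven paracellular leak at zero net flux too
  ins <- insert_config("i", ter = 5, apical_medium = "L15")
  des <- assay_design("CETA")
  sim <- simulate_insert(ins, transport_params(), des, cmp$terbutaline,
                         noise = NULL)
  expect_equal(sim$trajectories$conc_apical_nm,
               rep(sim$trajectories$conc_apical_nm[1], 5), tolerance = 1e-12)
  expect_equal(sim$trajectories$conc_basal_nm,
               rep(sim$trajectories$conc_basal_nm[1], 5), tolerance = 1e-12)
  # volumes shrink by one aliquot per sampling
  expect_equal(sim$trajectories$apical_volume_ml, 1.5 - 0.1 * (0:4))
  # mass is conserved exactly: dosed = remaining + removed ledger
  expect_equal(sum(sim$final[c("apical_pmol", "basal_pmol")]) + sum(sim$removed),
               sim$dosed, tolerance = 1e-9)
})

test_that("mass balance holds across assay modes and parameter sets", {
  designs <- list(assay_design("BTA", donor_side = "apical"),
                  assay_design("BTA", donor_side = "basal"),
                  assay_design("CETA"),
                  assay_design("mannitol"))
  drugs <- c("propranolol", "imipramine", "ranitidine", "mannitol")
  for (k in seq_along(designs)) {
    drug <- drugs[k]
    ins <- insert_config("i", ter = if (drug == "mannitol") 0.5 else 18.1,
                         apical_medium = "freshwater")
    sim <- simulate_insert(ins, default_transport_params(drug), designs[[k]],
                           cmp[[drug]], noise = NULL)
    total <- sum(sim$final[c("apical_pmol", "basal_pmol")]) + sum(sim$removed)
    expect_lt(abs(total - sim$dosed) / sim$dosed, 1e-6)
  }
})

test_that("simulated kinetics match the analytic two-compartment solution", {
  # passive-only, near-zero sampling losses: the numerical trajectory must
  # agree with the exponential closed form to 1e-8 relative
  p_trans <- 2e-5
  ins <- insert_config("i", ter = 2, apical_medium = "L15")
  pars <- transport_params(p_trans = p_trans)
  des <- assay_design("BTA", donor_side = "apical",
                      sampling_times = c(0, 6, 24, 48), aliquot_volume = 1e-11)
  sim <- simulate_insert(ins, pars, des, cmp$propranolol, noise = NULL)
  fn <- compound_neutral_fraction(cmp$propranolol, 7.4)
  p_eff <- p_trans * fn + paracellular_permeability(2)
  c0 <- mass_conc_to_molar(1, cmp$propranolol$molecular_weight)
  for (t in c(6, 24, 48)) {
    oracle <- analytic_two_comp(p_eff, 0.9, 1.5, 2.0, c0, 0, t)
    row <- sim$trajectories[sim$trajectories$time_h == t, ]
    expect_equal(row$conc_apical_nm, oracle$ca, tolerance = 1e-8)
    expect_equal(row$conc_basal_nm, oracle$cb, tolerance = 1e-8)
  }
})

test_that("an apical uptake carrier raises uptake Papp and the uptake TR", {
  base <- transport_params(p_trans = 2e-5)
  with_carrier <- transport_params(p_trans = 2e-5, uptake_jmax = 5e-5,
                                   uptake_km = 50)
  papp_of <- function(pars, donor) {
    rec <- sim_bta_records("propranolol", "L15", donor, params = pars)
    papp_6h(rec, cmp$propranolol)$papp_cm_per_s
  }
  ab0 <- papp_of(base, "apical");        ba0 <- papp_of(base, "basal")
  ab1 <- papp_of(with_carrier, "apical"); ba1 <- papp_of(with_carrier, "basal")
  expect_gt(ab1, ab0)
  expect_gt(ab1 / ba1, ab0 / ba0)
  # symmetric passive-only: directions identical, TR = 1
  expect_equal(ab0, ba0, tolerance = 1e-9)
  expect_equal(transport_ratio(ab0, ba0)$uptake_tr, 1, tolerance = 1e-9)
})

test_that("noise-free base uptake is non-decreasing in apical pH", {
  papp_at_ph <- function(ph) {
    rec <- sim_bta_records("propranolol", "freshwater", "apical",
                           apical_ph = ph)
    papp_6h(rec, cmp$propranolol)$papp_cm_per_s
  }
  vals <- vapply(c(6, 7, 8, 9.5), papp_at_ph, numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("seeded noisy simulations are reproducible and noise-free ones deterministic", {
  ins <- insert_config("i", ter = 18.1, apical_medium = "freshwater")
  des <- assay_design("BTA", donor_side = "apical")
  pars <- default_transport_params("propranolol")
  s1 <- simulate_insert(ins, pars, des, cmp$propranolol, noise = noise_model(),
                        seed = 99)
  s2 <- simulate_insert(ins, pars, des, cmp$propranolol, noise = noise_model(),
                        seed = 99)
  expect_identical(s1$records, s2$records)
  expect_true(all(s1$records$dpm == round(s1$records$dpm)))  # Poisson counts
  d1 <- simulate_insert(ins, pars, des, cmp$propranolol, noise = NULL)
  d2 <- simulate_insert(ins, pars, des, cmp$propranolol, noise = NULL)
  expect_identical(d1$records, d2$records)
})
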