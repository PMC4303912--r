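cmp <- gill_compounds()

test_that("TER gate retains developed epithelia, keeping ties and order", {
  ins <- data.frame(insert_id = c("a", "b", "c"), ter = c(3.0, 5.0, 18.1))
  expect_equal(ter_gate(ins), c("b", "c"))
  expect_equal(ter_gate(data.frame(insert_id = character(0), ter = numeric(0))),
               character(0))
  expect_equal(ter_gate(data.frame(insert_id = "x", ter = 4.9)), character(0))
  # idempotent and order-preserving
  shuffled <- ins[c(3, 1, 2), ]
  kept <- ter_gate(shuffled)
  expect_equal(kept, c("c", "b"))
  expect_equal(ter_gate(shuffled[shuffled$insert_id %in% kept, ]), kept)
  expect_error(ter_gate(data.frame(insert_id = "x", ter = -1)))
})

test_that("mannitol permeability formula inverts the blank-insert value", {
  expect_equal(mannitol_permeability(41057, 2.2e5, 1.5, 24, 0.9), 3.6e-6,
               tolerance = 1e-3)
  expect_equal(mannitol_permeability(0, 2.2e5), 0)
  expect_error(mannitol_permeability(10, 0))
  expect_error(mannitol_permeability(10, 100, area = 0))
  expect_error(mannitol_permeability(10, 100, duration_h = 0))
})

test_that("Papp estimator inverts the reported uptake permeability", {
  # donor apical 1.5 mL at 1 ug/L; receiver gains 0.0525 ng over 6 h
  mw <- cmp$propranolol$molecular_weight
  sa <- cmp$propranolol$specific_activity
  c0 <- mass_conc_to_molar(1, mw)                   # nM
  gain_pmol <- 0.0525 / mw * 1000                   # 0.0525 ng as pmol
  c_r6 <- gain_pmol / (2.0 - 0.1)                   # receiver conc at 6 h
  rec <- data.frame(
    insert_id = "i1", donor_side = "apical",
    compartment = rep(c("apical", "basal"), 2),
    time_h = c(0, 0, 6, 6), aliquot_volume_ml = 0.1,
    dpm = amount_to_dpm(c(c0, 0, NA, c_r6) * 0.1, sa))
  rec$dpm[3] <- amount_to_dpm(c0 * 0.95 * 0.1, sa)  # donor at 6 h (unused)
  pr <- papp_6h(rec, cmp$propranolol)
  expect_equal(pr$papp_cm_per_s, 2.7e-6, tolerance = 1e-3)
  expect_equal(pr$direction, "A:B")
  # zero receiver gain gives zero Papp
  rec0 <- rec
  rec0$dpm[c(2, 4)] <- 0
  expect_equal(papp_6h(rec0, cmp$propranolol)$papp_cm_per_s, 0)
  # missing required samples are named
  expect_error(papp_6h(rec[rec$time_h != 0, ], cmp$propranolol), "t = 0")
  expect_error(papp_6h(rec[rec$time_h != 6, ], cmp$propranolol), "t = 6")
})

test_that("Papp recovers the simulator permeability under sink conditions", {
  # passive-only oracle: effective permeability is p_trans * f_n + p_para
  p_trans <- 2e-5
  rec <- sim_bta_records("propranolol", "L15", "apical",
                         params = transport_params(p_trans = p_trans))
  fn <- compound_neutral_fraction(cmp$propranolol, 7.4)
  p_eff <- p_trans * fn + paracellular_permeability(18.1)
  est <- papp_6h(rec, cmp$propranolol)$papp_cm_per_s
  expect_equal(est, p_eff, tolerance = 0.05)
  # donor depletion over the window stays below 10%
  donor0 <- rec$dpm[rec$compartment == "apical" & rec$time_h == 0]
  donor6 <- rec$dpm[rec$compartment == "apical" & rec$time_h == 6]
  expect_gt(donor6 / donor0, 0.9)
})

test_that("drug Papp and mannitol permeability are the same estimator", {
  # blank insert (TER 0), mannitol assay, noise off
  ins <- insert_config("blank", ter = 0, apical_medium = "freshwater")
  sim <- simulate_insert(ins, default_transport_params("mannitol"),
                         assay_design("mannitol"), cmp$mannitol, noise = NULL)
  r <- sim$records
  aliquot <- r$aliquot_volume_ml[1]
  dpm_of <- function(compn, t) r$dpm[r$compartment == compn & r$time_h == t]
  m_ap <- dpm_of("apical", 0) / aliquot * 1.5
  m_bl_end <- dpm_of("basal", 24) / aliquot * (2.0 - aliquot) + dpm_of("basal", 0)
  delta <- m_bl_end - dpm_of("basal", 0) / aliquot * 2.0
  p_eq1 <- mannitol_permeability(delta, m_ap, 1.5, 24, 0.9)
  p_eq2 <- papp_6h(r, cmp$mannitol, at_time = 24)$papp_cm_per_s
  expect_equal(p_eq1, p_eq2, tolerance = 1e-9)
  # blank-tier magnitude: the 24-h two-point estimate sits below the
  # instantaneous 3.6e-6 because ~19% of the dose equilibrates
  expect_equal(p_eq1, 3.6e-6, tolerance = 0.2)
})

test_that("transport ratios classify active transport at the 1.5 threshold", {
  tr1 <- transport_ratio(1e-6, 1e-6)
  expect_equal(tr1$uptake_tr, 1)
  expect_equal(tr1$efflux_tr, 1)
  expect_false(tr1$active_uptake || tr1$active_efflux)
  tr2 <- transport_ratio(3.21e-6, 1e-6)
  expect_true(tr2$active_uptake)
  expect_false(tr2$active_efflux)
  # ties classify as active (>= rule)
  expect_true(transport_ratio(1.5e-6, 1e-6)$active_uptake)
  # uptake x efflux = 1 for any pair
  set.seed(4)
  for (i in 1:25) {
    pair <- runif(2, 1e-8, 1e-5)
    tr <- transport_ratio(pair[1], pair[2])
    expect_equal(tr$uptake_tr * tr$efflux_tr, 1, tolerance = 1e-12)
  }
  expect_error(transport_ratio(1e-6, 0), "zero")
  expect_error(transport_ratio(-1e-6, 1e-6), "upstream")
})

test_that("BTA percent-of-donor starts at 100/0 and tracks facilitated uptake", {
  rec <- sim_bta_records("propranolol", "freshwater", "apical")
  pd <- percent_of_donor(rec)
  expect_equal(pd$percent_initial_donor[pd$role == "donor" & pd$time_h == 0], 100)
  expect_equal(pd$percent_initial_donor[pd$role == "receiver" & pd$time_h == 0], 0)
  # uptake curve exceeds the efflux curve at every sampling time from 6 h on
  rec_eff <- sim_bta_records("propranolol", "freshwater", "basal")
  pd_eff <- percent_of_donor(rec_eff)
  for (t in c(6, 24, 30, 48)) {
    up <- pd$percent_initial_donor[pd$role == "receiver" & pd$time_h == t]
    ef <- pd_eff$percent_initial_donor[pd_eff$role == "receiver" & pd_eff$time_h == t]
    expect_gt(up, ef)
  }
  expect_error(percent_of_donor(rec[rec$time_h != 0, ]), "t = 0")
})

test_that("CETA percent-of-initial exposes carrier-mediated redistribution", {
  cmp_p <- cmp$propranolol
  ins <- insert_config("c1", ter = 18.1, apical_medium = "freshwater")
  sim <- simulate_insert(ins, default_transport_params("propranolol"),
                         assay_design("CETA"), cmp_p, noise = NULL)
  pc <- ceta_percent_initial(sim$records)
  expect_equal(pc$percent_initial[pc$time_h == 0], c(100, 100))
  # facilitated uptake: basal rises above 100%, apical falls below
  expect_gt(pc$percent_initial[pc$compartment == "basal" & pc$time_h == 48], 100)
  expect_lt(pc$percent_initial[pc$compartment == "apical" & pc$time_h == 48], 100)
})

test_that("inhibition is expressed as percent of the mean control", {
  ctl <- c(2.5e-6, 2.7e-6, 2.9e-6)
  expect_equal(inhibition_percent_of_control(mean(ctl), ctl), 100)
  expect_equal(inhibition_percent_of_control(0.699 * mean(ctl), ctl), 69.9)
  # controls expressed against their own mean average to 100
  expect_equal(mean(inhibition_percent_of_control(ctl, ctl)), 100)
  expect_error(inhibition_percent_of_control(1e-6, numeric(0)))
  expect_error(inhibition_percent_of_control(1e-6, c(-2e-6, 1e-6)))
})

test_that("equal-variance t-test matches hand computation and conventions", {
  res <- ttest_equal_var(c(1, 2, 3), c(2, 3, 4))
  expect_equal(res$t, -1.2247, tolerance = 1e-4)
  expect_equal(res$df, 4)
  expect_gt(res$p, 0.05)
  same <- ttest_equal_var(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  const <- ttest_equal_var(c(2, 2), c(2, 2))
  expect_equal(const$p, 1)
  expect_error(ttest_equal_var(c(1, 1), c(2, 2)), "degenerate")
  expect_error(ttest_equal_var(1, c(1, 2)))
})

test_that("a 3-SD group difference at n = 5 is detected in >95% of runs", {
  set.seed(2026)
  hits <- 0L
  n_rep <- 300L
  for (i in seq_len(n_rep)) {
    g1 <- rnorm(5, 0, 1)
    g2 <- rnorm(5, 3, 1)
    if (ttest_equal_var(g1, g2)$p < 0.05) hits <- hits + 1L
  }
  expect_gt(hits / n_rep, 0.95)
})

test_that("one-way ANOVA on logs matches brute-force sums of squares", {
  groups <- list(c(1.2, 1.5, 1.9, 2.2), c(2.5, 2.8, 3.3), c(0.9, 1.1, 1.0, 1.3))
  res <- anova_log(groups)
  oracle <- anova_by_sums_of_squares(lapply(groups, log))
  expect_equal(res$f, oracle$f, tolerance = 1e-10)
  expect_equal(res$p, oracle$p, tolerance = 1e-10)
  expect_equal(res$df1, 2)
  expect_equal(res$df2, 8)
  # identical groups: no between-group signal
  same <- anova_log(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$f, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-12)
  # two groups: F equals t^2 of the pooled t-test on logs
  g1 <- c(1.1, 1.9, 2.4, 3.0); g2 <- c(2.2, 2.9, 3.8)
  f2 <- anova_log(list(g1, g2))
  t2 <- ttest_equal_var(log(g1), log(g2))
  expect_equal(f2$f, t2$t^2, tolerance = 1e-10)
  expect_equal(f2$p, t2$p, tolerance = 1e-10)
  expect_error(anova_log(list(c(1, -2, 3), c(1, 2, 3))), "log")
  expect_error(anova_log(list(c(1, 2, 3))))
})
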