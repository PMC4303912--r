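# Independent oracles, deliberately separate from the package's code paths.

# Analytic solution of the passive two-compartment system with fixed volumes:
# dNa/dt = -k (Ca - Cb), dNb/dt = +k (Ca - Cb) with k = P * A (cm^3/s).
# Concentration difference decays exponentially; total mass is conserved.
analytic_two_comp <- function(p_eff_cm_s, area, va, vb, ca0, cb0, t_h) {
  k <- p_eff_cm_s * area * 3600          # mL/h
  m <- ca0 * va + cb0 * vb
  ceq <- m / (va + vb)
  lambda <- k * (1 / va + 1 / vb)
  ca <- ceq + (ca0 - ceq) * exp(-lambda * t_h)
  cb <- (m - ca * va) / vb
  list(ca = ca, cb = cb)
}

# Brute-force OLS via the normal equations.
ols_normal_equations <- function(X, y) {
  drop(solve(t(X) %*% X, t(X) %*% y))
}

# Hand-computed one-way ANOVA from sums of squares.
anova_by_sums_of_squares <- function(groups) {
  all_vals <- unlist(groups)
  grand <- mean(all_vals)
  ss_between <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2,
                           numeric(1)))
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- length(groups) - 1
  df2 <- length(all_vals) - length(groups)
  f <- (ss_between / df1) / (ss_within / df2)
  list(f = f, p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

# A noise-free BTA simulation, returning records, for metric tests.
sim_bta_records <- function(drug = "propranolol", medium = "L15",
                            donor = "apical", params = NULL,
                            apical_ph = NULL, ter = 18.1,
                            inhibitor = NULL, dose = 1,
                            times = c(0, 6, 24, 30, 48)) {
  cmp <- gill_compounds()[[drug]]
  if (is.null(params)) params <- default_transport_params(drug)
  ins <- insert_config("t1", ter = ter, apical_medium = medium,
                       apical_ph = apical_ph)
  des <- assay_design("BTA", donor_side = donor, dose_ug_per_l = dose,
                      sampling_times = times, inhibitor = inhibitor)
  simulate_insert(ins, params, des, cmp, noise = NULL)$records
}
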