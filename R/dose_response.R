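# Concentration-response regression and the fish plasma read-across
# comparison: linear and quadratic OLS fits of uptake flux against exposure
# concentration, the blood-water partition prediction for propranolol, and
# regressions of in-vitro basal concentrations on predicted and measured
# plasma levels.

#' Predicted fish plasma concentration from a water concentration
#'
#' Blood-water partition model for propranolol: plasma = 0.87 x water
#' concentration (ug/L in water equals ng/mL in plasma numerically).
#'
#' @param water_conc Water concentration in ug/L (>= 0, vectorized).
#' @return Predicted plasma concentration in ng/mL.
#' @examples
#' predict_plasma(1000)  # 870 ng/mL
#' @export
predict_plasma <- function(water_conc) {
  if (any(water_conc < 0)) stop("water concentration must be >= 0")
  0.87 * water_conc
}

.regression_fit <- function(model, coefficients, r_squared, n) {
  structure(list(model = model, coefficients = coefficients,
                 r_squared = r_squared, n = n),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  co <- paste(sprintf("%s = %.4g", names(x$coefficients), x$coefficients),
              collapse = ", ")
  cat(sprintf("<regression_fit> %s: %s (r^2 = %.4f, n = %d)\n",
              x$model, co, x$r_squared, x$n))
  invisible(x)
}

#' Ordinary least squares linear fit
#'
#' OLS of y on x, with or without an intercept. The coefficient of
#' determination is computed against the fitted model (for a through-origin
#' fit, relative to the uncentered total sum of squares).
#'
#' @param x,y Numeric vectors of equal length.
#' @param through_origin Force the fit through the origin?
#' @return A `regression_fit` with `model` `"linear_origin"` or
#'   `"linear_intercept"`, named `coefficients`, `r_squared` and `n`.
#' @export
fit_linear <- function(x, y, through_origin = FALSE) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 2L || (!through_origin && n < 3L)) stop("too few points for the fit")
  if (stats::var(x) == 0) stop("degenerate x: zero variance")
  if (!through_origin && stats::var(y) == 0) stop("degenerate y: zero variance")
  if (through_origin) {
    fit <- stats::lm(y ~ x + 0)
    co <- c(slope = unname(stats::coef(fit)))
    model <- "linear_origin"
  } else {
    fit <- stats::lm(y ~ x)
    co <- c(intercept = unname(stats::coef(fit)[1]),
            slope = unname(stats::coef(fit)[2]))
    model <- "linear_intercept"
  }
  # exact fits trip summary.lm's "essentially perfect fit" warning; r^2 = 1
  # is a legitimate outcome here
  .regression_fit(model, co, suppressWarnings(summary(fit)$r.squared), n)
}

#' Second-order polynomial fit over the low concentration range
#'
#' Quadratic OLS on the points at or below `max_conc`, reported alongside the
#' nested linear fit's r-squared for model comparison; curvature in the low
#' (environmentally relevant) range is the signature of a saturable uptake
#' component superimposed on passive transport.
#'
#' @param conc Concentrations (ug/L).
#' @param flux Response (receiver gain rate at the Papp time, per insert).
#' @param max_conc Upper edge of the low range (default 0.14 ug/L).
#' @return A `regression_fit` with `model` `"poly2"`, coefficients
#'   `(intercept, c1, c2)`, and an extra element `linear_r_squared`.
#' @export
fit_poly2_low_range <- function(conc, flux, max_conc = 0.14) {
  keep <- conc <= max_conc
  x <- conc[keep]; y <- flux[keep]
  if (length(x) < 4L) stop("at least 4 points are required in the low range")
  if (stats::var(x) == 0) stop("degenerate x: zero variance")
  if (stats::var(y) == 0) stop("degenerate y: zero variance")
  fit <- stats::lm(y ~ x + I(x^2))
  lin <- stats::lm(y ~ x)
  out <- .regression_fit("poly2",
                         c(intercept = unname(stats::coef(fit)[1]),
                           c1 = unname(stats::coef(fit)[2]),
                           c2 = unname(stats::coef(fit)[3])),
                         suppressWarnings(summary(fit)$r.squared), length(x))
  out$linear_r_squared <- suppressWarnings(summary(lin)$r.squared)
  out
}

#' Simulate the concentration-response experiment from its fitted line
#'
#' Surrogate generator for parameter-recovery checks: draws per-insert uptake
#' fluxes from the through-origin linear model `flux = slope x concentration`
#' with multiplicative lognormal noise of the given coefficient of
#' variation, over the 17-level design (n = 54 by default).
#'
#' @param slope Generating slope (flux units per ug/L; default 0.052).
#' @param concentrations Concentration levels (ug/L).
#' @param n_per_level Inserts per level (recycled to the number of levels).
#' @param cv Multiplicative noise CV (default 0.10).
#' @param seed Integer seed (mandatory).
#' @return Data frame: `insert_id`, `concentration_ug_per_l`, `flux`.
#' @export
simulate_concentration_response <- function(slope = 0.052,
                                            concentrations = concentration_series(),
                                            n_per_level = concentration_series_n(),
                                            cv = 0.10, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (cv < 0) stop("cv must be >= 0")
  set.seed(seed)
  conc <- rep(concentrations, rep_len(n_per_level, length(concentrations)))
  sdlog <- if (cv > 0) sqrt(log(1 + cv^2)) else 0
  noise <- if (sdlog > 0) exp(stats::rnorm(length(conc), 0, sdlog)) else 1
  data.frame(insert_id = sprintf("conc_i%02d", seq_along(conc)),
             concentration_ug_per_l = conc,
             flux = slope * conc * noise,
             stringsAsFactors = FALSE)
}

#' Read a plasma comparison table
#'
#' CSV with columns `nominal_water_ug_per_l, in_silico_ng_per_ml,
#' in_vivo_ng_per_ml, in_vivo_sem, in_vitro_ng_per_ml, in_vitro_sem`;
#' missing in-vivo measurements are empty/NA cells.
#'
#' @param path Path to the CSV.
#' @return Data frame with those columns.
#' @export
read_plasma_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("nominal_water_ug_per_l", "in_silico_ng_per_ml",
            "in_vivo_ng_per_ml", "in_vitro_ng_per_ml")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("plasma table lacks columns: ", paste(missing, collapse = ", "))
  }
  tab
}

#' Built-in plasma comparison table
#'
#' Mean in-vitro basal propranolol concentrations at 6 h across seven
#' nominal water concentrations (0.1 to 100,000 ug/L), alongside predicted
#' (0.87 x water) and, where available, measured rainbow trout plasma
#' concentrations.
#'
#' @return Data frame (7 rows).
#' @export
gill_plasma_table <- function() {
  read_plasma_table(system.file("extdata", "plasma_comparison.csv",
                                package = "gillflux", mustWork = TRUE))
}

#' Regress in-vitro basal concentrations on predicted and measured plasma
#'
#' Fits in_vitro ~ predicted over all rows with an in-silico value and
#' in_vitro ~ actual over rows with a measured plasma concentration
#' (missing in-vivo cells are excluded pairwise). Each comparison needs at
#' least three overlapping rows. The two slopes summarize how far the static
#' 6-h in-vitro system sits below the steady-state plasma levels.
#'
#' @param table A plasma comparison table (see [gill_plasma_table()]).
#' @param through_origin Fit through the origin instead of with intercept?
#' @return List: `vs_predicted` and `vs_actual` ([fit_linear()] fits), and
#'   `slopes` (named numeric of the two slopes).
#' @export
compare_in_vitro_plasma <- function(table, through_origin = FALSE) {
  ok_pred <- stats::complete.cases(table$in_silico_ng_per_ml,
                                   table$in_vitro_ng_per_ml)
  ok_act <- stats::complete.cases(table$in_vivo_ng_per_ml,
                                  table$in_vitro_ng_per_ml)
  if (sum(ok_pred) < 3L || sum(ok_act) < 3L) {
    stop("each comparison needs at least 3 overlapping rows")
  }
  fp <- fit_linear(table$in_silico_ng_per_ml[ok_pred],
                   table$in_vitro_ng_per_ml[ok_pred],
                   through_origin = through_origin)
  fa <- fit_linear(table$in_vivo_ng_per_ml[ok_act],
                   table$in_vitro_ng_per_ml[ok_act],
                   through_origin = through_origin)
  list(vs_predicted = fp, vs_actual = fa,
       slopes = c(vs_predicted = unname(fp$coefficients["slope"]),
                  vs_actual = unname(fa$coefficients["slope"])))
}
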