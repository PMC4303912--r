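# Estimators and decision rules: TER gating, mannitol and drug apparent
# permeability, transport ratios, time-course readouts, inhibitor
# percent-of-control, and the study's hypothesis tests.

#' Analysis configuration
#'
#' Thresholds and options used across the estimators: the TER development
#' gate (5 kOhm cm^2), the active-transport threshold on transport ratios
#' (1.5), the Papp evaluation time (6 h), the significance level (0.05) and
#' whether ANOVA log-transforms its input.
#'
#' @param ter_threshold kOhm cm^2; inserts at or above it are retained.
#' @param tr_threshold Transport-ratio threshold for the active flag.
#' @param papp_time Hours over which the receiver gain rate is taken.
#' @param alpha Two-sided significance level.
#' @param log_transform_anova Log-transform data before one-way ANOVA?
#' @return An `analysis_config` object.
#' @export
analysis_config <- function(ter_threshold = 5, tr_threshold = 1.5,
                            papp_time = 6, alpha = 0.05,
                            log_transform_anova = TRUE) {
  if (ter_threshold <= 0 || tr_threshold <= 0 || papp_time <= 0 || alpha <= 0) {
    stop("thresholds must be > 0")
  }
  structure(list(ter_threshold = ter_threshold, tr_threshold = tr_threshold,
                 papp_time = papp_time, alpha = alpha,
                 log_transform_anova = log_transform_anova),
            class = "analysis_config")
}

#' Gate inserts on transepithelial resistance
#'
#' Epithelia are considered developed and electrically tight once TER
#' reaches the threshold; only those inserts enter transport assays. Ties at
#' exactly the threshold are retained. Order-preserving and idempotent.
#'
#' @param inserts Data frame with columns `insert_id` and `ter` (kOhm cm^2),
#'   or a named numeric vector of TER values.
#' @param config An [analysis_config()].
#' @return Character vector of retained insert ids (possibly empty).
#' @export
ter_gate <- function(inserts, config = analysis_config()) {
  if (is.numeric(inserts)) {
    inserts <- data.frame(insert_id = names(inserts), ter = unname(inserts))
  }
  if (nrow(inserts) == 0L) return(character(0))
  if (any(inserts$ter < 0)) stop("ter must be >= 0")
  as.character(inserts$insert_id[inserts$ter >= config$ter_threshold])
}

#' Mannitol (paracellular marker) permeability
#'
#' Radioactivity-based permeability of the paracellular marker: the basal
#' gain in dpm over the assay, scaled by the donor volume and normalized by
#' the initial apical radioactivity, time and membrane area. The volume is
#' the donor (apical) volume, which makes the formula dimensionally
#' identical to the drug Papp estimator with C0 = M_AP / V_donor.
#'
#' @param delta_m_bl Change in basal-compartment radioactivity (dpm).
#' @param m_ap Initial apical radioactivity (dpm, > 0).
#' @param donor_volume Donor (apical) volume in mL.
#' @param duration_h Assay duration in hours.
#' @param area Membrane area in cm^2.
#' @return Permeability in cm/s.
#' @export
mannitol_permeability <- function(delta_m_bl, m_ap, donor_volume = 1.5,
                                  duration_h = 24, area = 0.9) {
  if (any(m_ap <= 0)) stop("m_ap must be > 0")
  if (any(duration_h <= 0)) stop("duration must be > 0")
  if (any(area <= 0)) stop("area must be > 0")
  if (any(donor_volume <= 0)) stop("donor volume must be > 0")
  delta_m_bl * donor_volume / (m_ap * duration_h * 3600 * area)
}

# Sorted sampling times and compartment concentrations (nM) for one insert.
.insert_conc <- function(records, compound) {
  conc <- dpm_to_amount(records$dpm, compound$specific_activity) /
    records$aliquot_volume_ml
  data.frame(time_h = records$time_h, compartment = records$compartment,
             conc_nm = conc, stringsAsFactors = FALSE)
}

#' Apparent permeability from the sampling records of one insert
#'
#' Computes the receiver-compartment amount gain rate over 0 to `at_time`
#' hours and normalizes by membrane area and the initial donor
#' concentration: Papp = (dQ/dt) / (A C0) / 3600, in cm/s. The receiver
#' amount Q(t) is the compartment concentration times its current volume
#' (volumes shrink by one aliquot per sampling) plus, by default, the
#' cumulative amount carried away in earlier aliquots.
#'
#' @param records Sampling records of a single BTA insert (both compartments,
#'   at least times 0 and `at_time`).
#' @param compound The [compound_record()] assayed (for dpm conversion).
#' @param config An [analysis_config()]; `config$papp_time` is the default
#'   evaluation time.
#' @param at_time Evaluation time in hours.
#' @param apical_volume,basal_volume Initial compartment volumes (mL).
#' @param area Membrane area (cm^2).
#' @param correct_aliquots Add back amounts removed in earlier receiver
#'   aliquots (default) or ignore them (sensitivity mode).
#' @return A `papp_result` list: `insert_id`, `direction` (`"A:B"` or
#'   `"B:A"`), `papp_cm_per_s`, `dq_dt_pmol_per_h`, `c0_nm`, `area`,
#'   `at_time`.
#' @export
papp_6h <- function(records, compound, config = analysis_config(),
                    at_time = config$papp_time, apical_volume = 1.5,
                    basal_volume = 2.0, area = 0.9, correct_aliquots = TRUE) {
  stopifnot(inherits(compound, "compound_record"))
  ids <- unique(records$insert_id)
  if (length(ids) != 1L) stop("papp_6h expects records from exactly one insert")
  donor <- unique(records$donor_side)
  if (length(donor) != 1L || !donor %in% c("apical", "basal")) {
    stop("records must carry a single donor_side of 'apical' or 'basal'")
  }
  receiver <- if (donor == "apical") "basal" else "apical"
  conc <- .insert_conc(records, compound)
  times <- sort(unique(conc$time_h))
  get_conc <- function(comp, t) {
    v <- conc$conc_nm[conc$compartment == comp & conc$time_h == t]
    if (length(v) != 1L) {
      stop("missing required sample: ", comp, " compartment at t = ", t, " h")
    }
    v
  }
  if (!0 %in% times) stop("missing required sample: donor compartment at t = 0 h")
  if (!at_time %in% times) {
    stop("missing required sample: receiver compartment at t = ", at_time, " h")
  }
  c0 <- get_conc(donor, 0)
  if (c0 <= 0) stop("initial donor concentration must be > 0")
  v0 <- if (receiver == "apical") apical_volume else basal_volume
  aliquot <- unique(records$aliquot_volume_ml)[1]
  q_at <- function(t) {
    k <- match(t, times)                      # k-th sampling event
    v_now <- v0 - aliquot * (k - 1L)          # volume before this sampling
    q <- get_conc(receiver, t) * v_now
    if (correct_aliquots && k > 1L) {
      prev <- times[seq_len(k - 1L)]
      q <- q + sum(vapply(prev, function(tp) get_conc(receiver, tp), numeric(1))) * aliquot
    }
    q
  }
  dq_dt <- (q_at(at_time) - q_at(0)) / at_time   # pmol/h
  papp <- dq_dt / (area * c0) / 3600
  structure(list(insert_id = ids, direction = if (donor == "apical") "A:B" else "B:A",
                 papp_cm_per_s = papp, dq_dt_pmol_per_h = dq_dt, c0_nm = c0,
                 area = area, at_time = at_time),
            class = "papp_result")
}

#' Per-insert Papp table for a sampling-record dataset
#'
#' Applies the TER gate, then computes one Papp per BTA insert at the
#' configured time.
#'
#' @param records Sampling-record data frame (any number of inserts; only
#'   BTA-mode rows are used).
#' @param compounds Compound table (default [gill_compounds()]).
#' @param config An [analysis_config()].
#' @param at_time Evaluation time (hours).
#' @param apply_gate Apply the TER gate before estimating?
#' @return Data frame with one row per retained insert: identifiers,
#'   direction, Papp, flux rate and initial donor concentration.
#' @export
papp_table <- function(records, compounds = gill_compounds(),
                       config = analysis_config(),
                       at_time = config$papp_time, apply_gate = TRUE) {
  bta <- records[records$mode == "BTA", , drop = FALSE]
  if (nrow(bta) == 0L) return(NULL)
  if (apply_gate) {
    ins <- unique(bta[, c("insert_id", "ter_kohm_cm2")])
    keep <- ter_gate(data.frame(insert_id = ins$insert_id,
                                ter = ins$ter_kohm_cm2), config)
    bta <- bta[bta$insert_id %in% keep, , drop = FALSE]
    if (nrow(bta) == 0L) return(NULL)
  }
  rows <- lapply(split(bta, bta$insert_id), function(r) {
    comp <- compounds[[r$drug[1]]]
    if (is.null(comp)) stop("compound '", r$drug[1], "' not in compound table")
    pr <- papp_6h(r, comp, config, at_time = at_time)
    data.frame(insert_id = pr$insert_id, scenario = r$scenario[1],
               drug = r$drug[1], condition = r$condition[1],
               donor_side = r$donor_side[1], direction = pr$direction,
               inhibitor = r$inhibitor[1], inhibitor_side = r$inhibitor_side[1],
               apical_ph = r$apical_ph[1], ter_kohm_cm2 = r$ter_kohm_cm2[1],
               papp_cm_s = pr$papp_cm_per_s,
               dq_dt_pmol_per_h = pr$dq_dt_pmol_per_h, c0_nm = pr$c0_nm,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Transport ratios and active-transport classification
#'
#' Uptake TR = Papp(A:B) / Papp(B:A); efflux TR is its reciprocal. A ratio
#' at or above the threshold (default 1.5) flags carrier-mediated transport
#' in that direction.
#'
#' @param papp_ab,papp_ba Directional apparent permeabilities (> 0).
#' @param config An [analysis_config()].
#' @return A `tr_result` list: `uptake_tr`, `efflux_tr`, `active_uptake`,
#'   `active_efflux`, `threshold`.
#' @export
transport_ratio <- function(papp_ab, papp_ba, config = analysis_config()) {
  if (papp_ba == 0 || papp_ab == 0) {
    stop("transport ratio undefined: zero Papp")
  }
  if (papp_ba < 0 || papp_ab < 0) {
    stop("negative Papp must be resolved upstream of transport_ratio")
  }
  up <- papp_ab / papp_ba
  structure(list(uptake_tr = up, efflux_tr = 1 / up,
                 active_uptake = up >= config$tr_threshold,
                 active_efflux = (1 / up) >= config$tr_threshold,
                 threshold = config$tr_threshold),
            class = "tr_result")
}

#' Time course as percent of the initial donor concentration (BTA)
#'
#' Expresses each compartment's concentration at each sampling time as a
#' percentage of the donor compartment's concentration at t = 0.
#'
#' @param records Sampling records of one BTA insert.
#' @return Data frame: `compartment`, `role` (donor/receiver), `time_h`,
#'   `percent_initial_donor`.
#' @export
percent_of_donor <- function(records) {
  donor <- unique(records$donor_side)
  if (length(donor) != 1L || !donor %in% c("apical", "basal")) {
    stop("records must carry a single donor_side")
  }
  d0 <- records$dpm[records$compartment == donor & records$time_h == 0]
  if (length(d0) != 1L) stop("missing required sample: donor compartment at t = 0 h")
  if (d0 <= 0) stop("initial donor concentration must be > 0")
  data.frame(compartment = records$compartment,
             role = ifelse(records$compartment == donor, "donor", "receiver"),
             time_h = records$time_h,
             percent_initial_donor = 100 * records$dpm / d0,
             stringsAsFactors = FALSE)
}

#' Time course as percent of each compartment's own initial level (CETA)
#'
#' Both compartments are dosed at t = 0; any systematic divergence from 100%
#' indicates carrier-mediated transport independent of the concentration
#' gradient.
#'
#' @param records Sampling records of one CETA insert.
#' @return Data frame: `compartment`, `time_h`, `percent_initial`.
#' @export
ceta_percent_initial <- function(records) {
  out <- lapply(c("apical", "basal"), function(comp) {
    r <- records[records$compartment == comp, , drop = FALSE]
    c0 <- r$dpm[r$time_h == 0]
    if (length(c0) != 1L) stop("missing required sample: ", comp, " at t = 0 h")
    if (c0 <= 0) stop("initial ", comp, " concentration must be > 0")
    data.frame(compartment = comp, time_h = r$time_h,
               percent_initial = 100 * r$dpm / c0, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Inhibitor effect as percent of the mean control Papp
#'
#' @param papp_treated Papp values measured with inhibitor.
#' @param papp_controls Inhibitor-free control Papp values (mean must be
#'   positive).
#' @return Numeric vector: 100 x treated / mean(controls).
#' @export
inhibition_percent_of_control <- function(papp_treated, papp_controls) {
  if (length(papp_controls) < 1L) stop("at least one control is required")
  m <- mean(papp_controls)
  if (m <= 0) stop("mean control Papp must be > 0")
  100 * papp_treated / m
}

#' Independent-samples t-test with equal variances assumed
#'
#' Pooled-variance two-sided t-test. Two identical constant groups return
#' t = 0, p = 1 by convention; constant groups with different means are
#' degenerate and rejected.
#'
#' @param group1,group2 Numeric vectors, each of length >= 2.
#' @return List: `t`, `df`, `p`.
#' @export
ttest_equal_var <- function(group1, group2) {
  if (length(group1) < 2L || length(group2) < 2L) {
    stop("each group needs n >= 2")
  }
  n1 <- length(group1); n2 <- length(group2)
  pooled <- ((n1 - 1) * stats::var(group1) + (n2 - 1) * stats::var(group2)) /
    (n1 + n2 - 2)
  if (pooled == 0) {
    if (mean(group1) == mean(group2)) {
      return(list(t = 0, df = n1 + n2 - 2, p = 1))
    }
    stop("zero pooled variance with unequal means: degenerate input")
  }
  ht <- stats::t.test(group1, group2, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' One-way ANOVA on log-transformed data
#'
#' Natural-log transforms all values (they must be positive), then fits a
#' one-way ANOVA across the groups. All-identical data return F = 0, p = 1
#' by convention.
#'
#' @param groups List of numeric vectors (>= 2 groups).
#' @param log_transform Log-transform before fitting (default TRUE, the
#'   study's convention)?
#' @return List: `f`, `df1`, `df2`, `p`.
#' @export
anova_log <- function(groups, log_transform = TRUE) {
  if (length(groups) < 2L) stop("at least two groups are required")
  vals <- unlist(groups, use.names = FALSE)
  if (log_transform) {
    if (any(vals <= 0)) {
      stop("all values must be > 0 for the log transform")
    }
    groups <- lapply(groups, log)
    vals <- unlist(groups, use.names = FALSE)
  }
  g <- factor(rep(seq_along(groups), lengths(groups)))
  df1 <- length(groups) - 1L
  df2 <- length(vals) - length(groups)
  if (df2 < 1L) stop("not enough replication for ANOVA")
  if (stats::var(vals) == 0) return(list(f = 0, df1 = df1, df2 = df2, p = 1))
  fit <- stats::aov(vals ~ g)
  tab <- summary(fit)[[1]]
  if (is.na(tab[1, "F value"])) {
    stop("degenerate ANOVA: zero within-group variance with unequal means")
  }
  list(f = tab[1, "F value"], df1 = df1, df2 = df2, p = tab[1, "Pr(>F)"])
}
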