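# End-to-end orchestration: simulate -> gate -> estimate -> classify -> fit,
# with CSV report writers. Each stage logs one line with row counts so runs
# are auditable; everything is deterministic given the dataset (and, for
# simulation, the seed).

.log_stage <- function(stage, ..., quiet = FALSE) {
  if (!quiet) message(sprintf("[gillflux] %s: %s", stage, sprintf(...)))
}

#' Simulate a sampling-record dataset (pipeline front end)
#'
#' Thin wrapper over [generate_dataset()] that logs a dataset census and
#' optionally writes the records CSV.
#'
#' @param catalog Scenario catalog (default [paper_catalog()]).
#' @param seed Integer master seed.
#' @param noise A [noise_model()] or `NULL`.
#' @param scenarios Optional scenario-name subset.
#' @param out Optional path for the records CSV.
#' @param quiet Suppress log lines?
#' @return The sampling-record data frame, invisibly if `out` is given.
#' @export
run_simulation <- function(catalog = paper_catalog(), seed,
                           noise = noise_model(), scenarios = NULL,
                           out = NULL, quiet = FALSE) {
  records <- generate_dataset(catalog, seed = seed, noise = noise,
                              scenarios = scenarios)
  .log_stage("simulate", "seed %d, %d scenarios, %d inserts, %d records",
             seed, length(unique(records$scenario)),
             length(unique(records$insert_id)), nrow(records), quiet = quiet)
  if (!is.null(out)) {
    utils::write.csv(records, out, row.names = FALSE)
    .log_stage("simulate", "wrote %s", out, quiet = quiet)
    return(invisible(records))
  }
  records
}

# Mannitol permeability per insert from mannitol-mode sampling records.
.mannitol_table <- function(records, compounds, config) {
  mrec <- records[records$mode == "mannitol", , drop = FALSE]
  if (nrow(mrec) == 0L) return(NULL)
  comp <- compounds[["mannitol"]]
  rows <- lapply(split(mrec, mrec$insert_id), function(r) {
    aliquot <- r$aliquot_volume_ml[1]
    times <- sort(unique(r$time_h))
    t_end <- max(times)
    dpm_of <- function(cmp, t) r$dpm[r$compartment == cmp & r$time_h == t]
    scale0 <- 2.0 / aliquot
    # basal radioactivity, corrected for the aliquot removed at t = 0
    m_bl_end <- dpm_of("basal", t_end) / aliquot * (2.0 - aliquot) +
      dpm_of("basal", 0)
    delta <- m_bl_end - dpm_of("basal", 0) * scale0
    m_ap <- dpm_of("apical", 0) / aliquot * 1.5
    data.frame(insert_id = r$insert_id[1], ter_kohm_cm2 = r$ter_kohm_cm2[1],
               permeability_cm_s = mannitol_permeability(delta, m_ap, 1.5,
                                                         t_end, 0.9),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$ter_kohm_cm2), ]
}

# Mean Papp per (drug, condition, direction) over the plain BTA scenarios,
# then one transport ratio per drug x condition.
.tr_table <- function(papp, config) {
  core <- papp[grepl("_bta_(uptake|efflux)$", papp$scenario), , drop = FALSE]
  if (nrow(core) == 0L) return(NULL)
  agg <- stats::aggregate(papp_cm_s ~ drug + condition + direction,
                          data = core, FUN = mean)
  rows <- list()
  for (d in unique(agg$drug)) {
    for (cond in unique(agg$condition[agg$drug == d])) {
      ab <- agg$papp_cm_s[agg$drug == d & agg$condition == cond &
                            agg$direction == "A:B"]
      ba <- agg$papp_cm_s[agg$drug == d & agg$condition == cond &
                            agg$direction == "B:A"]
      if (length(ab) != 1L || length(ba) != 1L) next
      tr <- transport_ratio(ab, ba, config)
      rows[[length(rows) + 1L]] <- data.frame(
        drug = d, condition = cond, papp_ab_cm_s = ab, papp_ba_cm_s = ba,
        uptake_tr = tr$uptake_tr, efflux_tr = tr$efflux_tr,
        active_uptake = tr$active_uptake, active_efflux = tr$active_efflux,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Percent-of-control per (inhibitor, side, time) from inhibitor scenarios.
.inhibition_table <- function(records, compounds, config) {
  inh_rec <- records[records$mode == "BTA" &
                       (grepl("inhibitor", records$scenario)), , drop = FALSE]
  if (nrow(inh_rec) == 0L) return(NULL)
  times <- setdiff(sort(unique(inh_rec$time_h)), 0)
  rows <- list()
  for (t in times) {
    pt <- papp_table(inh_rec, compounds, config, at_time = t)
    ctl <- pt$papp_cm_s[is.na(pt$inhibitor)]
    if (length(ctl) == 0L) next
    trt <- pt[!is.na(pt$inhibitor), , drop = FALSE]
    if (nrow(trt) == 0L) next
    pct <- inhibition_percent_of_control(trt$papp_cm_s, ctl)
    agg <- stats::aggregate(pct, by = list(inhibitor = trt$inhibitor,
                                           side = trt$inhibitor_side),
                            FUN = mean)
    rows[[length(rows) + 1L]] <- data.frame(
      inhibitor = agg$inhibitor, side = agg$side, time_h = t,
      pct_of_control = agg$x, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (!is.null(out)) out <- out[order(out$inhibitor, out$side, out$time_h), ]
  rownames(out) <- NULL
  out
}

# Through-origin concentration-response fit from the concentration-series
# scenario: receiver gain rate vs exposure concentration, plus the low-range
# quadratic-vs-linear comparison.
.conc_response <- function(papp, compounds) {
  cs <- papp[grepl("concentration_series", papp$scenario), , drop = FALSE]
  if (nrow(cs) == 0L) return(NULL)
  mw <- compounds[[cs$drug[1]]]$molecular_weight
  conc <- molar_to_mass_conc(cs$c0_nm, mw)
  flux <- cs$dq_dt_pmol_per_h
  list(data = data.frame(insert_id = cs$insert_id,
                         concentration_ug_per_l = conc, flux_pmol_per_h = flux,
                         stringsAsFactors = FALSE),
       linear_fit = fit_linear(conc, flux, through_origin = TRUE),
       low_range_fit = fit_poly2_low_range(conc, flux))
}

# Mean CETA percent-of-initial per scenario x compartment x time.
.ceta_table <- function(records) {
  crec <- records[records$mode == "CETA", , drop = FALSE]
  if (nrow(crec) == 0L) return(NULL)
  per <- lapply(split(crec, crec$insert_id), function(r) {
    p <- ceta_percent_initial(r)
    p$scenario <- r$scenario[1]
    p$drug <- r$drug[1]
    p$condition <- r$condition[1]
    p
  })
  all <- do.call(rbind, per)
  agg <- stats::aggregate(percent_initial ~ scenario + drug + condition +
                            compartment + time_h, data = all, FUN = mean)
  agg[order(agg$scenario, agg$compartment, agg$time_h), ]
}

#' Analyze a sampling-record dataset
#'
#' Chains the full estimation pipeline over a records data frame (simulated
#' or measured): TER gating, per-insert Papp at the configured time,
#' transport ratios with active-transport flags, mannitol permeability,
#' CETA percent-of-initial summaries, inhibitor percent-of-control time
#' courses, the through-origin concentration-response fit with the low-range
#' quadratic comparison, and the plasma read-across regressions. The gate is
#' applied before any Papp computation.
#'
#' @param records Sampling-record data frame.
#' @param compounds Compound table (default [gill_compounds()]).
#' @param config An [analysis_config()].
#' @param plasma_table Plasma comparison table (default the built-in one);
#'   `NULL` skips the plasma comparison.
#' @param quiet Suppress log lines?
#' @return A `gill_analysis` list: `papp`, `tr`, `mannitol`, `ceta`,
#'   `inhibition`, `conc_response`, `plasma`, `gated_out`, `config`.
#' @export
run_analysis <- function(records, compounds = gill_compounds(),
                         config = analysis_config(),
                         plasma_table = gill_plasma_table(), quiet = FALSE) {
  need <- c("insert_id", "scenario", "drug", "condition", "mode",
            "donor_side", "compartment", "time_h", "aliquot_volume_ml",
            "dpm", "ter_kohm_cm2")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    stop("records lack required columns: ", paste(missing_cols, collapse = ", "))
  }
  bad <- which(records$dpm < 0 | records$time_h < 0)
  if (length(bad)) {
    stop("invalid records at rows: ", paste(utils::head(bad, 5), collapse = ", "))
  }
  ins <- unique(records[records$mode != "mannitol",
                        c("insert_id", "ter_kohm_cm2")])
  kept <- ter_gate(data.frame(insert_id = ins$insert_id,
                              ter = ins$ter_kohm_cm2), config)
  gated_out <- setdiff(ins$insert_id, kept)
  .log_stage("gate", "TER >= %g kOhm cm2: kept %d of %d inserts",
             config$ter_threshold, length(kept), nrow(ins), quiet = quiet)
  papp <- papp_table(records, compounds, config)
  .log_stage("papp", "%d per-insert Papp estimates at %g h",
             if (is.null(papp)) 0L else nrow(papp), config$papp_time,
             quiet = quiet)
  tr <- if (!is.null(papp)) .tr_table(papp, config) else NULL
  mann <- .mannitol_table(records, compounds, config)
  ceta <- .ceta_table(records)
  inhib <- .inhibition_table(records, compounds, config)
  conc <- if (!is.null(papp)) .conc_response(papp, compounds) else NULL
  plasma <- if (!is.null(plasma_table)) compare_in_vitro_plasma(plasma_table)
            else NULL
  .log_stage("analyze", "tr rows %d, mannitol %d, ceta %d, inhibition %d",
             if (is.null(tr)) 0L else nrow(tr),
             if (is.null(mann)) 0L else nrow(mann),
             if (is.null(ceta)) 0L else nrow(ceta),
             if (is.null(inhib)) 0L else nrow(inhib), quiet = quiet)
  structure(list(papp = papp, tr = tr, mannitol = mann, ceta = ceta,
                 inhibition = inhib, conc_response = conc, plasma = plasma,
                 gated_out = gated_out, config = config),
            class = "gill_analysis")
}

#' Write report tables and print a human-readable summary
#'
#' Renders the analysis as CSV files (per-insert Papp, transport-ratio
#' matrix, inhibition table, fit summaries, plasma comparison) and prints a
#' transport-ratio matrix with active-transport flags plus the regression
#' summaries. A pure function of its input: the same analysis always
#' produces the same files.
#'
#' @param analysis A `gill_analysis` from [run_analysis()].
#' @param out_dir Optional directory for the CSV files.
#' @return Invisibly, the list of written file paths.
#' @export
run_report <- function(analysis, out_dir = NULL) {
  stopifnot(inherits(analysis, "gill_analysis"))
  written <- character(0)
  wr <- function(df, name) {
    if (is.null(df) || is.null(out_dir)) return()
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    written <<- c(written, path)
  }
  if (!is.null(analysis$tr)) {
    cat("Transport ratios (/* marks TR >= ",
        analysis$config$tr_threshold, "):\n", sep = "")
    tr <- analysis$tr
    mat <- data.frame(
      drug = tr$drug, condition = tr$condition,
      uptake_tr = sprintf("%.2f%s", tr$uptake_tr,
                          ifelse(tr$active_uptake, "*", "")),
      efflux_tr = sprintf("%.2f%s", tr$efflux_tr,
                          ifelse(tr$active_efflux, "*", "")))
    print(mat, row.names = FALSE)
  }
  if (!is.null(analysis$conc_response)) {
    cat("\nConcentration-response (through origin): slope ",
        format(analysis$conc_response$linear_fit$coefficients["slope"],
               digits = 3),
        ", r^2 ", format(analysis$conc_response$linear_fit$r_squared,
                         digits = 3), "\n", sep = "")
    cat("Low range: poly2 r^2 ",
        format(analysis$conc_response$low_range_fit$r_squared, digits = 3),
        " vs linear r^2 ",
        format(analysis$conc_response$low_range_fit$linear_r_squared,
               digits = 3), "\n", sep = "")
  }
  if (!is.null(analysis$plasma)) {
    cat("\nPlasma comparison slopes: in_vitro = ",
        format(analysis$plasma$slopes["vs_predicted"], digits = 3),
        " x predicted; in_vitro = ",
        format(analysis$plasma$slopes["vs_actual"], digits = 3),
        " x actual\n", sep = "")
  }
  wr(analysis$papp, "papp.csv")
  wr(analysis$tr, "transport_ratios.csv")
  wr(analysis$mannitol, "mannitol_permeability.csv")
  wr(analysis$ceta, "ceta_percent_initial.csv")
  wr(analysis$inhibition, "inhibition_percent_of_control.csv")
  if (!is.null(analysis$conc_response)) {
    wr(analysis$conc_response$data, "concentration_response.csv")
    cf <- analysis$conc_response$linear_fit
    lf <- analysis$conc_response$low_range_fit
    fits <- data.frame(
      model = c(cf$model, "poly2_low_range", "linear_low_range"),
      slope = c(cf$coefficients["slope"], lf$coefficients["c1"], NA),
      r_squared = c(cf$r_squared, lf$r_squared, lf$linear_r_squared),
      n = c(cf$n, lf$n, lf$n))
    wr(fits, "concentration_fits.csv")
  }
  if (!is.null(analysis$plasma)) {
    pf <- analysis$plasma
    plasma_fits <- data.frame(
      comparison = c("vs_predicted", "vs_actual"),
      slope = unname(pf$slopes),
      intercept = c(pf$vs_predicted$coefficients["intercept"],
                    pf$vs_actual$coefficients["intercept"]),
      r_squared = c(pf$vs_predicted$r_squared, pf$vs_actual$r_squared),
      n = c(pf$vs_predicted$n, pf$vs_actual$n))
    wr(plasma_fits, "plasma_fits.csv")
  }
  invisible(written)
}

#' Reproduce the full synthetic study
#'
#' Simulates the complete scenario catalog at the given seed, runs the
#' analysis pipeline, and (optionally) writes all report tables.
#'
#' @param seed Integer master seed.
#' @param out_dir Optional output directory.
#' @param noise A [noise_model()] or `NULL` for noise-free data.
#' @param quiet Suppress log lines?
#' @return List with `records` and `analysis`.
#' @export
reproduce_study <- function(seed, out_dir = NULL, noise = noise_model(),
                            quiet = FALSE) {
  records <- run_simulation(seed = seed, noise = noise, quiet = quiet)
  analysis <- run_analysis(records, quiet = quiet)
  run_report(analysis, out_dir = out_dir)
  invisible(list(records = records, analysis = analysis))
}
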