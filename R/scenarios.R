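# Scenario catalog and dataset generation: the full synthetic study design
# (seven drugs x conditions x assay modes, pH series, concentration series,
# inhibitor series, mannitol/TER sweep).

#' Default kinetic parameters per compound
#'
#' Calibration fixtures: parameter sets chosen so that noise-free simulated
#' apparent permeabilities approximate the measured study values
#' (propranolol 1.7e-6 cm/s symmetric A:B, 2.7e-6 asymmetric A:B, 0.8e-6
#' asymmetric B:A; imipramine 1.9e-6 symmetric and 3.0e-6 asymmetric A:B with
#' its uptake ratio crossing the 1.5 activity threshold only under apical
#' freshwater). Propranolol and imipramine carry saturable uptake carriers
#' (and weak efflux), metoprolol and atenolol carry efflux carriers, and
#' formoterol, terbutaline and ranitidine are passive-only. Propranolol's
#' inhibitor sensitivities reduce uptake-carrier capacity: cyclosporine A to
#' ~70% of control transport, MK571/quinidine to ~60%, cimetidine to the
#' model floor (carrier fully blocked), amantadine and verapamil inactive.
#'
#' @param drug Compound name (one of the seven pharmaceuticals or
#'   `"mannitol"`).
#' @return A [transport_params()] object.
#' @export
default_transport_params <- function(drug) {
  switch(drug,
    propranolol = transport_params(
      p_trans = 3.011e-05, asym_bias = 2.282,
      uptake_jmax = 7.083e-05, uptake_km = 50,
      efflux_jmax = 2.693e-06, efflux_km = 50,
      inhibitor_sensitivity = list(
        amantadine     = list(target = "uptake", fraction_remaining = 1.0),
        cimetidine     = list(target = "uptake", fraction_remaining = 0.0),
        cyclosporine_a = list(target = "uptake", fraction_remaining = 0.382),
        mk571          = list(target = "uptake", fraction_remaining = 0.179),
        quinidine      = list(target = "uptake", fraction_remaining = 0.179),
        verapamil      = list(target = "uptake", fraction_remaining = 1.0)
      )),
    imipramine = transport_params(
      p_trans = 3.152e-05, asym_bias = 2.29,
      uptake_jmax = 7.970e-05, uptake_km = 50,
      efflux_jmax = 4.821e-05, efflux_km = 50),
    metoprolol = transport_params(
      p_trans = 1.276e-04, asym_bias = 2.29,
      efflux_jmax = 3.762e-05, efflux_km = 50),
    atenolol = transport_params(
      p_trans = 1.595e-06, asym_bias = 2.29,
      efflux_jmax = 2.688e-06, efflux_km = 50),
    formoterol = transport_params(p_trans = 1.012e-04),
    terbutaline = transport_params(p_trans = 2.143e-04),
    ranitidine = transport_params(p_trans = 6.365e-06),
    mannitol = transport_params(p_trans = 0),
    stop("no default transport parameters for drug '", drug, "'")
  )
}

#' Define one named simulation scenario
#'
#' @param name Scenario name (unique within a catalog).
#' @param drug Compound name.
#' @param condition `"symmetric"` (culture medium both sides) or
#'   `"asymmetric"` (freshwater apical).
#' @param mode `"BTA"`, `"CETA"` or `"mannitol"`.
#' @param donor_side `"apical"` or `"basal"` (BTA).
#' @param n_inserts Number of inserts.
#' @param dose_ug_per_l Dose; scalar, or one value per insert (concentration
#'   series).
#' @param apical_ph Optional apical pH override (pH series).
#' @param inhibitor,inhibitor_side Optional inhibitor name and application
#'   side.
#' @param ter TER in kOhm cm^2; scalar or per-insert vector.
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(name, drug, condition = c("symmetric", "asymmetric"),
                          mode = c("BTA", "CETA", "mannitol"),
                          donor_side = "apical", n_inserts = 4,
                          dose_ug_per_l = 1, apical_ph = NULL,
                          inhibitor = NULL, inhibitor_side = "apical",
                          ter = 18.1) {
  condition <- match.arg(condition)
  mode <- match.arg(mode)
  if (length(dose_ug_per_l) > 1 && length(dose_ug_per_l) != n_inserts) {
    stop("dose_ug_per_l must be scalar or length n_inserts")
  }
  if (length(ter) > 1 && length(ter) != n_inserts) {
    stop("ter must be scalar or length n_inserts")
  }
  structure(list(name = name, drug = drug, condition = condition, mode = mode,
                 donor_side = donor_side, n_inserts = n_inserts,
                 dose_ug_per_l = dose_ug_per_l, apical_ph = apical_ph,
                 inhibitor = inhibitor, inhibitor_side = inhibitor_side,
                 ter = ter),
            class = "scenario_spec")
}

#' The 17-level propranolol concentration series
#'
#' Eight log-spaced levels over the low range 0.014-0.14 ug/L and nine over
#' 0.5-10,000 ug/L.
#'
#' @return Numeric vector of 17 concentrations (ug/L).
#' @export
concentration_series <- function() {
  c(10^seq(log10(0.014), log10(0.14), length.out = 8),
    10^seq(log10(0.5), log10(10000), length.out = 9))
}

#' Inserts per concentration level in the concentration series
#'
#' Three inserts per level plus three extra at the top level: n = 54 in
#' total, with n = 24 in the low range.
#' @return Integer vector of length 17.
#' @export
concentration_series_n <- function() c(rep(3L, 16L), 6L)

#' The full synthetic study catalog
#'
#' Every assay design of the study as named scenarios: seven drugs x
#' symmetric/asymmetric x BTA uptake / BTA efflux / CETA; the propranolol pH
#' series (apical pH 6, 8, 9.5, both directions); the 17-level, 54-insert
#' propranolol concentration series; six inhibitors applied apically or
#' basally plus inhibitor-free controls; and a mannitol/TER sweep across 37
#' inserts from cell-free (TER 0) to fully tight epithelia.
#'
#' @return Named list of [scenario_spec()] objects.
#' @export
paper_catalog <- function() {
  drugs <- c("propranolol", "metoprolol", "atenolol", "formoterol",
             "terbutaline", "ranitidine", "imipramine")
  cat <- list()
  for (d in drugs) {
    for (cond in c("symmetric", "asymmetric")) {
      tag <- if (cond == "symmetric") "sym" else "asym"
      cat[[paste(d, tag, "bta_uptake", sep = "_")]] <-
        scenario_spec(paste(d, tag, "bta_uptake", sep = "_"), d, cond, "BTA",
                      donor_side = "apical")
      cat[[paste(d, tag, "bta_efflux", sep = "_")]] <-
        scenario_spec(paste(d, tag, "bta_efflux", sep = "_"), d, cond, "BTA",
                      donor_side = "basal")
      cat[[paste(d, tag, "ceta", sep = "_")]] <-
        scenario_spec(paste(d, tag, "ceta", sep = "_"), d, cond, "CETA")
    }
  }
  for (ph in c(6, 8, 9.5)) {
    for (ds in c("apical", "basal")) {
      nm <- sprintf("propranolol_ph%s_%s", format(ph), if (ds == "apical") "uptake" else "efflux")
      cat[[nm]] <- scenario_spec(nm, "propranolol", "asymmetric", "BTA",
                                 donor_side = ds, apical_ph = ph)
    }
  }
  conc <- rep(concentration_series(), concentration_series_n())
  cat[["propranolol_concentration_series"]] <-
    scenario_spec("propranolol_concentration_series", "propranolol",
                  "asymmetric", "BTA", donor_side = "apical",
                  n_inserts = length(conc), dose_ug_per_l = conc)
  inhibitors <- c("amantadine", "cimetidine", "cyclosporine_a", "mk571",
                  "quinidine", "verapamil")
  for (inh in inhibitors) {
    for (side in c("apical", "basal")) {
      nm <- sprintf("propranolol_inhibitor_%s_%s", inh, side)
      cat[[nm]] <- scenario_spec(nm, "propranolol", "asymmetric", "BTA",
                                 donor_side = "apical", inhibitor = inh,
                                 inhibitor_side = side)
    }
  }
  cat[["propranolol_inhibitor_control"]] <-
    scenario_spec("propranolol_inhibitor_control", "propranolol",
                  "asymmetric", "BTA", donor_side = "apical", n_inserts = 18)
  ters <- c(rep(0, 4), 0.2, 0.3, 0.5, 0.7, 0.9, 1.2, 1.5, 1.8,
            seq(2, 14, length.out = 25))
  cat[["mannitol_ter_sweep"]] <-
    scenario_spec("mannitol_ter_sweep", "mannitol", "asymmetric", "mannitol",
                  n_inserts = length(ters), ter = ters)
  cat
}

#' Generate a synthetic sampling-record dataset
#'
#' Runs every requested scenario through the kinetic simulator, one seeded
#' simulation per insert, and binds all sampling records. The same seed
#' always yields an identical dataset (per-insert seeds are drawn from a
#' master stream in catalog order, whether or not noise is enabled).
#'
#' @param catalog Named list of [scenario_spec()]s (default [paper_catalog()]).
#' @param seed Integer master seed (mandatory).
#' @param noise A [noise_model()], or `NULL` for noise-free data.
#' @param scenarios Optional character vector selecting scenarios by name;
#'   unknown names are an error.
#' @param compounds Compound table (default [gill_compounds()]).
#' @return Data frame of sampling records (one row per compartment per
#'   sampling time per insert).
#' @export
generate_dataset <- function(catalog = paper_catalog(), seed,
                             noise = noise_model(), scenarios = NULL,
                             compounds = gill_compounds()) {
  if (missing(seed)) stop("seed is mandatory")
  if (!is.null(scenarios)) {
    unknown <- setdiff(scenarios, names(catalog))
    if (length(unknown)) {
      stop("unknown scenario name(s): ", paste(unknown, collapse = ", "))
    }
    catalog <- catalog[scenarios]
  }
  set.seed(seed)
  n_total <- sum(vapply(catalog, function(s) s$n_inserts, numeric(1)))
  insert_seeds <- sample.int(2^31 - 2, max(n_total, 1))
  idx <- 0L
  out <- vector("list", length(catalog))
  for (j in seq_along(catalog)) {
    sc <- catalog[[j]]
    if (!sc$drug %in% names(compounds)) {
      stop("compound '", sc$drug, "' not in compound table")
    }
    compound <- compounds[[sc$drug]]
    params <- default_transport_params(sc$drug)
    doses <- rep_len(sc$dose_ug_per_l, sc$n_inserts)
    ters <- rep_len(sc$ter, sc$n_inserts)
    recs <- vector("list", sc$n_inserts)
    for (i in seq_len(sc$n_inserts)) {
      idx <- idx + 1L
      ins <- insert_config(
        insert_id = sprintf("%s_i%02d", sc$name, i), ter = ters[i],
        apical_medium = if (sc$condition == "asymmetric") "freshwater" else "L15",
        apical_ph = sc$apical_ph
      )
      des <- assay_design(
        mode = sc$mode, donor_side = sc$donor_side,
        dose_ug_per_l = doses[i],
        inhibitor = if (is.null(sc$inhibitor)) NULL else
          list(name = sc$inhibitor, side = sc$inhibitor_side, conc_nm = 400)
      )
      sim <- simulate_insert(ins, params, des, compound, noise = noise,
                             seed = insert_seeds[idx], scenario = sc$name,
                             replicate_id = sprintf("r%02d", i),
                             condition = sc$condition)
      recs[[i]] <- sim$records
    }
    out[[j]] <- do.call(rbind, recs)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write / read a scenario catalog as YAML
#'
#' Serializes the catalog (all scenario fields, units embedded in key names)
#' to a structured text config.
#'
#' @param catalog Named list of [scenario_spec()]s.
#' @param path File path.
#' @return `read_scenario_catalog()` returns the catalog.
#' @export
write_scenario_catalog <- function(catalog, path) {
  plain <- lapply(catalog, function(s) {
    s <- unclass(s)
    s[!vapply(s, is.null, logical(1))]
  })
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_scenario_catalog
#' @export
read_scenario_catalog <- function(path) {
  plain <- yaml::read_yaml(path)
  out <- lapply(plain, function(s) {
    do.call(scenario_spec, s[intersect(names(s), names(formals(scenario_spec)))])
  })
  names(out) <- vapply(out, function(s) s$name, character(1))
  out
}
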