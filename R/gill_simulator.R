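# Two-compartment kinetic simulator of the cultured gill epithelium.
#
# The epithelium separates an apical compartment (1.5 mL, freshwater or
# culture medium) from a basal compartment (2.0 mL, culture medium) across
# 0.9 cm^2 of membrane. Amounts are tracked in pmol, concentrations in nM
# (1 nM = 1 pmol/cm^3, so cm/s x cm^2 x nM gives pmol/s directly), volumes
# in mL (= cm^3) and time in hours at the interface, seconds inside flux
# terms.

#' Configure one epithelium insert
#'
#' Geometry, media and electrical state of one cultured insert. The apical
#' pH defaults to 7.4 in culture medium (L15) and 7.7 in freshwater (the
#' synthetic freshwater recipe); pH-series experiments override it.
#'
#' @param insert_id Identifier.
#' @param ter Transepithelial resistance in kOhm cm^2 (>= 0).
#' @param apical_medium `"L15"` or `"freshwater"`.
#' @param apical_volume,basal_volume Compartment volumes in mL.
#' @param area Membrane area in cm^2.
#' @param apical_ph Apical pH; `NULL` selects the medium default.
#' @param basal_ph Basal pH (culture medium, 7.4).
#' @param tep Transepithelial potential in mV (informational).
#' @return An `insert_config` object.
#' @export
insert_config <- function(insert_id, ter, apical_medium = c("L15", "freshwater"),
                          apical_volume = 1.5, basal_volume = 2.0, area = 0.9,
                          apical_ph = NULL, basal_ph = 7.4, tep = NA_real_) {
  apical_medium <- match.arg(apical_medium)
  if (apical_volume <= 0 || basal_volume <= 0) stop("volumes must be > 0")
  if (area <= 0) stop("area must be > 0")
  if (ter < 0) stop("ter must be >= 0")
  if (is.null(apical_ph)) {
    apical_ph <- if (apical_medium == "freshwater") 7.7 else 7.4
  }
  structure(list(
    insert_id = as.character(insert_id), ter = ter,
    apical_medium = apical_medium,
    apical_volume = apical_volume, basal_volume = basal_volume,
    area = area, apical_ph = apical_ph, basal_ph = basal_ph, tep = tep
  ), class = "insert_config")
}

#' Kinetic parameters of one compound on one epithelium
#'
#' Passive transcellular permeability of the neutral species, saturable
#' carrier-mediated uptake (apical to basal) and efflux (basal to apical)
#' with Michaelis-Menten kinetics, an electrical asymmetry bias applied to
#' passive permeation of bases under apical freshwater (the freshwater-
#' induced basolateral-negative potential aids cation partitioning), and
#' per-inhibitor sensitivities as fractional reduction of the targeted
#' carrier's jmax.
#'
#' @param p_trans Transcellular permeability of the neutral species (cm/s).
#' @param uptake_jmax,efflux_jmax Carrier capacities (pmol cm^-2 s^-1).
#' @param uptake_km,efflux_km Carrier half-saturation constants (nM, > 0).
#' @param asym_bias Multiplier (>= 1) on passive flux for basic compounds
#'   when the apical medium is freshwater.
#' @param inhibitor_sensitivity Named list; each element is
#'   `list(target = "uptake"|"efflux", fraction_remaining = f)` with f in
#'   `[0, 1]`.
#' @return A `transport_params` object.
#' @export
transport_params <- function(p_trans = 0, uptake_jmax = 0, uptake_km = 50,
                             efflux_jmax = 0, efflux_km = 50, asym_bias = 1,
                             inhibitor_sensitivity = list()) {
  if (p_trans < 0 || uptake_jmax < 0 || efflux_jmax < 0) {
    stop("permeability and jmax must be >= 0")
  }
  if (uptake_km <= 0 || efflux_km <= 0) stop("km must be > 0")
  if (asym_bias < 1) stop("asym_bias must be >= 1")
  for (s in inhibitor_sensitivity) {
    if (!s$target %in% c("uptake", "efflux")) stop("inhibitor target must be uptake or efflux")
    if (s$fraction_remaining < 0 || s$fraction_remaining > 1) {
      stop("fraction_remaining must lie in [0, 1]")
    }
  }
  structure(list(
    p_trans = p_trans,
    uptake_jmax = uptake_jmax, uptake_km = uptake_km,
    efflux_jmax = efflux_jmax, efflux_km = efflux_km,
    asym_bias = asym_bias,
    inhibitor_sensitivity = inhibitor_sensitivity
  ), class = "transport_params")
}

#' Describe one assay run on one insert
#'
#' @param mode `"BTA"` (one-sided dose), `"CETA"` (both compartments dosed at
#'   the same concentration) or `"mannitol"` (apical radiolabel dose, 0/24 h
#'   sampling).
#' @param donor_side `"apical"` (uptake, A:B) or `"basal"` (efflux, B:A);
#'   BTA only.
#' @param dose_ug_per_l Dose concentration in ug/L (default 1, the
#'   environmentally relevant test level).
#' @param dose_dpm Mannitol mode only: dosed radioactivity (default 2.2e5 dpm).
#' @param sampling_times Hours, strictly increasing from 0. Defaults:
#'   c(0, 6, 24, 30, 48); mannitol c(0, 24).
#' @param aliquot_volume Sampled volume per compartment per time (mL).
#' @param inhibitor Optional `list(name=, side=, conc_nm=)`; the side is
#'   informational (inhibition acts on carrier capacity regardless of side).
#' @return An `assay_design` object.
#' @export
assay_design <- function(mode = c("BTA", "CETA", "mannitol"),
                         donor_side = c("apical", "basal"),
                         dose_ug_per_l = 1, dose_dpm = 2.2e5,
                         sampling_times = NULL, aliquot_volume = 0.1,
                         inhibitor = NULL) {
  mode <- match.arg(mode)
  donor_side <- match.arg(donor_side)
  if (is.null(sampling_times)) {
    sampling_times <- if (mode == "mannitol") c(0, 24) else c(0, 6, 24, 30, 48)
  }
  if (sampling_times[1] != 0 || any(diff(sampling_times) <= 0)) {
    stop("sampling times must be strictly increasing and start at 0")
  }
  if (dose_ug_per_l < 0) stop("dose must be >= 0")
  if (aliquot_volume <= 0) stop("aliquot volume must be > 0")
  if (!is.null(inhibitor)) {
    stopifnot(is.list(inhibitor), !is.null(inhibitor$name))
    inhibitor$side <- match.arg(inhibitor$side, c("apical", "basal"))
  }
  structure(list(
    mode = mode, donor_side = donor_side, dose_ug_per_l = dose_ug_per_l,
    dose_dpm = dose_dpm, sampling_times = sampling_times,
    aliquot_volume = aliquot_volume, inhibitor = inhibitor
  ), class = "assay_design")
}

#' Measurement noise model
#'
#' Lognormal pipetting error on each aliquot (coefficient of variation
#' `pipetting_cv`) and Poisson counting noise on the recorded dpm.
#'
#' @param pipetting_cv Fractional CV of pipetted volume/amount (>= 0).
#' @param counting Apply Poisson noise to dpm?
#' @return A `noise_model` object.
#' @export
noise_model <- function(pipetting_cv = 0.05, counting = TRUE) {
  if (pipetting_cv < 0) stop("pipetting_cv must be >= 0")
  structure(list(pipetting_cv = pipetting_cv, counting = counting),
            class = "noise_model")
}

#' TER-dependent paracellular permeability
#'
#' Monotone non-increasing map from transepithelial resistance to the
#' paracellular (mannitol-equivalent) permeability, anchored at the measured
#' tiers: 3.6e-6 cm/s for cell-free inserts (TER 0), 1.1e-6 cm/s over
#' 0.2-1.0 kOhm cm^2, and 0.1e-6 cm/s for tight epithelia (TER >= 2
#' kOhm cm^2), with log-linear interpolation between anchors.
#'
#' @param ter TER in kOhm cm^2 (vectorized, >= 0).
#' @return Permeability in cm/s.
#' @export
paracellular_permeability <- function(ter) {
  if (any(ter < 0)) stop("ter must be >= 0")
  x <- c(0, 0.2, 1.0, 2.0)
  y <- log10(c(3.6e-6, 1.1e-6, 1.1e-6, 0.1e-6))
  10^stats::approx(x, y, xout = pmin(ter, 2), rule = 2)$y
}

#' Per-pathway transmembrane fluxes
#'
#' Evaluates the four flux pathways at given compartment concentrations,
#' signed apical-to-basal positive, in pmol/s:
#' passive transcellular flux of the neutral species (pH-speciated on each
#' side, with the electrical asymmetry bias for bases under apical
#' freshwater), TER-dependent paracellular leak of total compound, and
#' saturable carrier-mediated uptake and efflux driven by the donor-side
#' total concentration.
#'
#' @param conc_apical,conc_basal Total concentrations (nM, >= 0).
#' @param insert An [insert_config()].
#' @param params A [transport_params()].
#' @param compound A [compound_record()].
#' @param inhibitor Optional inhibitor name; scales the targeted carrier's
#'   jmax by its `fraction_remaining`.
#' @return List with `passive`, `paracellular`, `uptake`, `efflux`, `net`
#'   (pmol/s).
#' @export
flux_terms <- function(conc_apical, conc_basal, insert, params, compound,
                       inhibitor = NULL) {
  if (conc_apical < 0 || conc_basal < 0) stop("concentrations must be >= 0")
  fn_a <- compound_neutral_fraction(compound, insert$apical_ph)
  fn_b <- compound_neutral_fraction(compound, insert$basal_ph)
  bias <- if (insert$apical_medium == "freshwater" && is_base(compound)) {
    params$asym_bias
  } else 1
  a <- insert$area
  uj <- params$uptake_jmax
  ej <- params$efflux_jmax
  if (!is.null(inhibitor) && inhibitor %in% names(params$inhibitor_sensitivity)) {
    s <- params$inhibitor_sensitivity[[inhibitor]]
    if (s$target == "uptake") uj <- uj * s$fraction_remaining
    if (s$target == "efflux") ej <- ej * s$fraction_remaining
  }
  j_passive <- params$p_trans * a * bias * (fn_a * conc_apical - fn_b * conc_basal)
  j_para <- paracellular_permeability(insert$ter) * a * (conc_apical - conc_basal)
  j_uptake <- uj * a * conc_apical / (params$uptake_km + conc_apical)
  j_efflux <- -ej * a * conc_basal / (params$efflux_km + conc_basal)
  list(passive = j_passive, paracellular = j_para,
       uptake = j_uptake, efflux = j_efflux,
       net = j_passive + j_para + j_uptake + j_efflux)
}

# Right-hand side for deSolve: state = amounts (pmol), time in hours.
.gill_rhs <- function(t, y, p) {
  fl <- flux_terms(y[1] / p$va, y[2] / p$vb, p$insert, p$params, p$compound,
                   p$inhibitor)
  j <- fl$net * 3600  # pmol/h
  list(c(-j, j))
}

#' Simulate one assay on one insert
#'
#' Integrates the two-compartment mass balance between sampling times
#' (adaptive lsoda, rtol 1e-9 / atol 1e-12 on a pmol scale). At each
#' sampling time one aliquot is removed from each compartment: the aliquot
#' amount leaves the system into a removal ledger and the compartment volume
#' shrinks by the aliquot volume (samples are counted, not returned). The
#' recorded dpm is the aliquot's radioactivity, optionally perturbed by the
#' noise model; with `noise = NULL` the output is fully deterministic.
#'
#' @param insert An [insert_config()].
#' @param params A [transport_params()].
#' @param design An [assay_design()].
#' @param compound A [compound_record()].
#' @param noise A [noise_model()] or `NULL` for noise-free output.
#' @param seed Optional integer seed used when `noise` is given.
#' @param scenario,replicate_id,condition Labels carried into the records.
#' @return A `gill_simulation` list: `records` (one row per compartment per
#'   sampling time, the sampling-record schema), `trajectories`
#'   (pre-sampling concentrations), `removed` (per-compartment ledger, pmol),
#'   `dosed` (pmol), `final` (amounts and volumes).
#' @export
simulate_insert <- function(insert, params, design, compound, noise = NULL,
                            seed = NULL, scenario = NA_character_,
                            replicate_id = NA_character_,
                            condition = NULL) {
  stopifnot(inherits(insert, "insert_config"),
            inherits(params, "transport_params"),
            inherits(design, "assay_design"),
            inherits(compound, "compound_record"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(condition)) {
    condition <- if (insert$apical_medium == "freshwater") "asymmetric" else "symmetric"
  }
  if (design$aliquot_volume >= min(insert$apical_volume, insert$basal_volume)) {
    stop("aliquot volume must be smaller than the compartment volumes")
  }
  sa <- compound$specific_activity
  # initial amounts (pmol)
  if (design$mode == "mannitol") {
    n_a <- dpm_to_amount(design$dose_dpm, sa)
    n_b <- 0
  } else {
    c0 <- mass_conc_to_molar(design$dose_ug_per_l, compound$molecular_weight)
    if (design$mode == "CETA") {
      n_a <- c0 * insert$apical_volume
      n_b <- c0 * insert$basal_volume
    } else if (design$donor_side == "apical") {
      n_a <- c0 * insert$apical_volume; n_b <- 0
    } else {
      n_a <- 0; n_b <- c0 * insert$basal_volume
    }
  }
  dosed <- n_a + n_b
  va <- insert$apical_volume
  vb <- insert$basal_volume
  removed_a <- 0
  removed_b <- 0
  inhibitor_name <- if (is.null(design$inhibitor)) NULL else design$inhibitor$name
  times <- design$sampling_times
  rec <- vector("list", 2L * length(times))
  traj <- vector("list", length(times))
  sdlog <- if (!is.null(noise) && noise$pipetting_cv > 0) {
    sqrt(log(1 + noise$pipetting_cv^2))
  } else 0

  measure <- function(conc, v_aliquot) {
    amount <- conc * v_aliquot
    if (sdlog > 0) amount <- amount * exp(stats::rnorm(1, 0, sdlog))
    dpm <- amount_to_dpm(amount, sa)
    if (!is.null(noise) && noise$counting) dpm <- stats::rpois(1, dpm)
    dpm
  }

  for (k in seq_along(times)) {
    if (k > 1L) {
      p <- list(va = va, vb = vb, insert = insert, params = params,
                compound = compound, inhibitor = inhibitor_name)
      sol <- deSolve::lsoda(y = c(n_a, n_b), times = c(times[k - 1L], times[k]),
                            func = .gill_rhs, parms = p,
                            rtol = 1e-9, atol = 1e-12)
      if (attr(sol, "istate")[1] < 0) {
        stop("ODE integration failed between ", times[k - 1L], " and ",
             times[k], " h (istate ", attr(sol, "istate")[1], ")")
      }
      n_a <- sol[nrow(sol), 2L]
      n_b <- sol[nrow(sol), 3L]
      if (n_a < -1e-9 || n_b < -1e-9) stop("negative concentration: invariant breach")
      n_a <- max(n_a, 0); n_b <- max(n_b, 0)
    }
    c_a <- n_a / va
    c_b <- n_b / vb
    traj[[k]] <- data.frame(time_h = times[k], conc_apical_nm = c_a,
                            conc_basal_nm = c_b, apical_volume_ml = va,
                            basal_volume_ml = vb)
    dpm_a <- measure(c_a, design$aliquot_volume)
    dpm_b <- measure(c_b, design$aliquot_volume)
    base_row <- data.frame(
      insert_id = insert$insert_id, replicate_id = replicate_id,
      scenario = scenario, drug = compound$name, condition = condition,
      mode = design$mode,
      donor_side = if (design$mode == "BTA") design$donor_side
                   else if (design$mode == "mannitol") "apical" else "both",
      compartment = c("apical", "basal"), time_h = times[k],
      aliquot_volume_ml = design$aliquot_volume, dpm = c(dpm_a, dpm_b),
      ter_kohm_cm2 = insert$ter, apical_ph = insert$apical_ph,
      inhibitor = if (is.null(design$inhibitor)) NA_character_ else design$inhibitor$name,
      inhibitor_side = if (is.null(design$inhibitor)) NA_character_ else design$inhibitor$side,
      stringsAsFactors = FALSE
    )
    rec[[k]] <- base_row
    # aliquot removal: true amount leaves the system, volume shrinks
    removed_a <- removed_a + c_a * design$aliquot_volume
    removed_b <- removed_b + c_b * design$aliquot_volume
    n_a <- n_a - c_a * design$aliquot_volume
    n_b <- n_b - c_b * design$aliquot_volume
    va <- va - design$aliquot_volume
    vb <- vb - design$aliquot_volume
  }
  total <- n_a + n_b + removed_a + removed_b
  if (dosed > 0 && abs(total - dosed) / dosed > 1e-6) {
    stop(sprintf("mass balance violated: dosed %.6g pmol, accounted %.6g pmol",
                 dosed, total))
  }
  structure(list(
    records = do.call(rbind, rec[!vapply(rec, is.null, logical(1))]),
    trajectories = do.call(rbind, traj),
    removed = c(apical = removed_a, basal = removed_b),
    dosed = dosed,
    final = c(apical_pmol = n_a, basal_pmol = n_b,
              apical_volume_ml = va, basal_volume_ml = vb)
  ), class = "gill_simulation")
}
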