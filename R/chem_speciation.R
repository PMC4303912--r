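# Ionization, pH-corrected partitioning and radiolabel unit conversions.
# All concentrations are nmol/L (nM) internally; amounts are pmol; counting
# data are disintegrations per minute (dpm).

#' Disintegrations per minute per Curie
#'
#' Conversion constant for radiolabel bookkeeping: 1 Ci = 2.22e12 dpm.
#' @export
DPM_PER_CI <- 2.22e12

#' Fraction of a compound in the ionized form (Henderson-Hasselbalch)
#'
#' For a monoprotic site, the ionized fraction at a given pH. A base is
#' protonated (cationic) below its pKa; an acid is deprotonated (anionic)
#' above its pKa.
#'
#' @param pka Acid dissociation constant of the site (pH units).
#' @param ph pH at which to evaluate the speciation.
#' @param kind `"acid"` or `"base"`.
#' @return Ionized fraction in (0, 1).
#' @examples
#' ionized_fraction(9.42, 7.4, "base")  # ~0.99: a weak base at gill pH
#' @export
ionized_fraction <- function(pka, ph, kind) {
  stopifnot(length(pka) == 1L, length(ph) == 1L,
            is.finite(pka), is.finite(ph))
  kind <- match.arg(kind, c("acid", "base"))
  if (kind == "base") 1 / (1 + 10^(ph - pka)) else 1 / (1 + 10^(pka - ph))
}

#' Fraction of a compound in the neutral form
#'
#' Complement of [ionized_fraction()]. For compounds with several ionizable
#' sites (`pka` and `kind` vectors of equal length) sites are treated as
#' independent and the neutral fraction is the product of per-site neutral
#' fractions; this microspeciation-free approximation is standard when no
#' microconstants are available. A site of kind `"none"` (non-ionizable
#' marker compounds such as mannitol) contributes a factor of 1.
#'
#' @param pka Numeric vector of site pKa values (may be empty or NA for
#'   non-ionizable compounds when `kind` is `"none"`).
#' @param ph pH at which to evaluate.
#' @param kind Character vector matching `pka`: `"acid"`, `"base"` or `"none"`.
#' @return Neutral fraction in (0, 1].
#' @export
neutral_fraction <- function(pka, ph, kind) {
  stopifnot(length(ph) == 1L, is.finite(ph))
  if (length(pka) == 0L) return(1)
  stopifnot(length(kind) == length(pka))
  f <- 1
  for (i in seq_along(pka)) {
    k <- match.arg(kind[i], c("acid", "base", "none"))
    if (k == "none") next
    f <- f * (1 - ionized_fraction(pka[i], ph, k))
  }
  f
}

#' Percent ionized, rounded half-up to an integer
#'
#' Reporting convenience for discussion-style statements ("99% ionized").
#'
#' @inheritParams ionized_fraction
#' @return Integer percent.
#' @export
percent_ionized <- function(pka, ph, kind) {
  floor(100 * ionized_fraction(pka, ph, kind) + 0.5)
}

#' pH-corrected octanol-water distribution coefficient (log Dow)
#'
#' For a single ionizable site, `log_kow + log10(neutral_fraction)`: only the
#' neutral species is assumed to partition into octanol, so log Dow is always
#' at or below log Kow.
#'
#' @param log_kow Octanol-water partition coefficient (log10).
#' @inheritParams ionized_fraction
#' @return log Dow (dimensionless).
#' @export
log_dow_at_ph <- function(log_kow, pka, ph, kind) {
  stopifnot(is.finite(log_kow))
  log_kow + log10(neutral_fraction(pka, ph, kind))
}

#' Convert a mass concentration to molarity
#'
#' @param conc_ug_per_l Concentration in micrograms per litre (>= 0).
#' @param mw Molecular weight in g/mol (> 0).
#' @return Concentration in nmol/L (nM).
#' @examples
#' mass_conc_to_molar(1, 259.34)  # 1 ug/L propranolol is ~3.86 nM
#' @export
mass_conc_to_molar <- function(conc_ug_per_l, mw) {
  if (any(mw <= 0)) stop("molecular weight must be > 0")
  if (any(conc_ug_per_l < 0)) stop("concentration must be >= 0")
  conc_ug_per_l / mw * 1000
}

#' @rdname mass_conc_to_molar
#' @param conc_nm Concentration in nmol/L.
#' @export
molar_to_mass_conc <- function(conc_nm, mw) {
  if (any(mw <= 0)) stop("molecular weight must be > 0")
  conc_nm * mw / 1000
}

#' Convert counted radioactivity to a molar amount
#'
#' Uses the compound's specific activity and 1 Ci = 2.22e12 dpm.
#' `amount_to_dpm()` is the exact inverse.
#'
#' @param dpm Disintegrations per minute (>= 0).
#' @param specific_activity Specific activity in Ci/mmol (> 0).
#' @return Amount in pmol.
#' @export
dpm_to_amount <- function(dpm, specific_activity) {
  if (any(specific_activity <= 0)) stop("specific activity must be > 0")
  if (any(dpm < 0)) stop("dpm must be >= 0")
  dpm / (specific_activity * DPM_PER_CI) * 1e9
}

#' @rdname dpm_to_amount
#' @param amount_pmol Amount in pmol.
#' @export
amount_to_dpm <- function(amount_pmol, specific_activity) {
  if (any(specific_activity <= 0)) stop("specific activity must be > 0")
  amount_pmol * specific_activity * DPM_PER_CI / 1e9
}

#' Construct a compound record
#'
#' Physicochemical and radiolabel properties of one test compound: molecular
#' weight, ionizable sites, lipophilicity and specific activity, plus the
#' externally measured pH-adjusted log Kow and typical environmental level
#' where available (stored verbatim, never recomputed).
#'
#' @param name Compound name.
#' @param molecular_weight g/mol, > 0.
#' @param pka Numeric vector of site pKa values, each in (0, 14); may be
#'   empty only for non-ionizable compounds (`pka_kind = "none"`).
#' @param pka_kind Character vector: `"acid"`, `"base"` or `"none"`.
#' @param log_kow log10 octanol-water partition coefficient.
#' @param specific_activity Ci/mmol, > 0.
#' @param log_kow_measured Optional externally measured pH-adjusted log Kow.
#' @param environmental_ng_per_l Optional typical surface-water level (ng/L).
#' @return A `compound_record` object (list).
#' @export
compound_record <- function(name, molecular_weight, pka, pka_kind, log_kow,
                            specific_activity, log_kow_measured = NA_real_,
                            environmental_ng_per_l = NA_real_) {
  stopifnot(is.character(name), length(name) == 1L)
  if (molecular_weight <= 0) stop("molecular_weight must be > 0")
  if (specific_activity <= 0) stop("specific_activity must be > 0")
  pka <- as.numeric(pka)
  pka_kind <- as.character(pka_kind)
  ionizable <- pka_kind != "none"
  if (length(pka[ionizable]) == 0L && any(pka_kind != "none")) {
    stop("ionizable compounds need at least one pKa entry")
  }
  if (any(ionizable) && any(pka[ionizable] <= 0 | pka[ionizable] >= 14)) {
    stop("each pKa must lie in (0, 14)")
  }
  if (!all(pka_kind %in% c("acid", "base", "none"))) {
    stop("pka_kind must be 'acid', 'base' or 'none'")
  }
  structure(list(
    name = name,
    molecular_weight = molecular_weight,
    pka = pka[ionizable],
    pka_kind = pka_kind[ionizable],
    log_kow = log_kow,
    specific_activity = specific_activity,
    log_kow_measured = log_kow_measured,
    environmental_ng_per_l = environmental_ng_per_l
  ), class = "compound_record")
}

#' @export
print.compound_record <- function(x, ...) {
  sites <- if (length(x$pka)) {
    paste(sprintf("%s %.2f", x$pka_kind, x$pka), collapse = ", ")
  } else "none"
  cat(sprintf("<compound_record> %s  MW %.2f g/mol  pKa: %s  logKow %.2f  SA %.1f Ci/mmol\n",
              x$name, x$molecular_weight, sites, x$log_kow, x$specific_activity))
  invisible(x)
}

#' Neutral fraction of a compound at a given pH
#'
#' @param compound A [compound_record()].
#' @param ph pH.
#' @return Neutral fraction (product over ionizable sites).
#' @export
compound_neutral_fraction <- function(compound, ph) {
  stopifnot(inherits(compound, "compound_record"))
  neutral_fraction(compound$pka, ph, compound$pka_kind)
}

#' Is any ionizable site of a compound basic?
#' @param compound A [compound_record()].
#' @return Logical.
#' @export
is_base <- function(compound) {
  stopifnot(inherits(compound, "compound_record"))
  any(compound$pka_kind == "base")
}

#' Read a compound property table
#'
#' CSV with columns `name, mw_g_per_mol, pka, pka_kind, log_kow,
#' log_kow_measured, specific_activity_ci_per_mmol, environmental_ng_per_l`.
#' Multi-site compounds list pKa values and kinds semicolon-separated.
#'
#' @param path Path to the CSV.
#' @return Named list of [compound_record()] objects.
#' @export
read_compound_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "mw_g_per_mol", "pka", "pka_kind", "log_kow",
            "specific_activity_ci_per_mmol")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("compound table lacks columns: ", paste(missing, collapse = ", "))
  }
  out <- lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    pka_str <- trimws(strsplit(as.character(row$pka), ";")[[1]])
    kind <- trimws(strsplit(row$pka_kind, ";")[[1]])
    pka <- suppressWarnings(as.numeric(pka_str))
    if (all(kind == "none")) pka <- numeric(0) else kind <- rep_len(kind, length(pka))
    compound_record(
      name = row$name,
      molecular_weight = row$mw_g_per_mol,
      pka = pka,
      pka_kind = if (length(pka)) kind else "none",
      log_kow = row$log_kow,
      specific_activity = row$specific_activity_ci_per_mmol,
      log_kow_measured = if ("log_kow_measured" %in% names(tab))
        row$log_kow_measured else NA_real_,
      environmental_ng_per_l = if ("environmental_ng_per_l" %in% names(tab))
        row$environmental_ng_per_l else NA_real_
    )
  })
  names(out) <- tab$name
  out
}

#' Built-in compound table
#'
#' The seven study pharmaceuticals (propranolol, metoprolol, atenolol,
#' formoterol, terbutaline, ranitidine, imipramine) plus the paracellular
#' marker mannitol, with molecular weights, pKa values, log Kow and
#' radiolabel specific activities.
#'
#' @return Named list of [compound_record()] objects.
#' @export
gill_compounds <- function() {
  read_compound_table(system.file("extdata", "compounds.csv",
                                  package = "gillflux", mustWork = TRUE))
}
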