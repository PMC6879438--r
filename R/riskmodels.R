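#' MIPI / MIPI-b scoring constants
#'
#' Coefficients and category cutpoints of the Mantle cell lymphoma
#' International Prognostic Index (classic and biological variants), exposed
#' as a config block so they are auditable and overridable:
#' `score = age_coef * age + ecog_coef * [ECOG >= 2] +
#'  ldh_coef * log10(LDH/ULN) + wbc_coef * log10(WBC in 1e6/L)`
#' (MIPI-b adds `ki67_coef * Ki-67 in %`). Categories: score < `cut[1]` low
#' (1), `cut[1] <= score < cut[2]` intermediate (2), `>= cut[2]` high (3).
#'
#' @return nested list with `mipi` and `mipi_b` blocks.
#' @export
mipi_constants <- function() {
  list(
    mipi = list(age = 0.03535, ecog = 0.6978, ldh = 1.367, wbc = 0.9393,
                cut = c(5.7, 6.2)),
    mipi_b = list(age = 0.03535, ecog = 0.6978, ldh = 1.367, wbc = 0.9393,
                  ki67 = 0.02142, cut = c(5.7, 6.5))
  )
}

score_to_category <- function(score, cut) {
  ifelse(score < cut[1], 1L, ifelse(score < cut[2], 2L, 3L))
}

#' Classic MIPI score and risk category
#'
#' @param age years.
#' @param ecog ECOG performance status 0-4 (scored as the indicator ECOG >= 2).
#' @param ldh lactate dehydrogenase, U/L.
#' @param ldh_uln upper limit of normal for LDH, U/L.
#' @param wbc white blood cell count, 1e9/L (converted internally to 1e6/L).
#' @param constants see [mipi_constants()].
#' @return data.frame with `score` and `category` (1 low, 2 intermediate,
#'   3 high). Vectorized over patients.
#' @export
mipi_score <- function(age, ecog, ldh, ldh_uln, wbc,
                       constants = mipi_constants()$mipi) {
  if (any(ldh <= 0) || any(ldh_uln <= 0)) stop_ctx("LDH and its ULN must be positive")
  if (any(wbc <= 0)) stop_ctx("WBC must be positive")
  score <- constants$age * age + constants$ecog * (ecog >= 2) +
    constants$ldh * log10(ldh / ldh_uln) + constants$wbc * log10(wbc * 1000)
  data.frame(score = score, category = score_to_category(score, constants$cut))
}

#' Biological MIPI (MIPI-b) score and risk category
#'
#' The classic MIPI linear predictor plus the Ki-67 proliferation index term.
#'
#' @inheritParams mipi_score
#' @param ki67 Ki-67 proliferation index, percent (0-100).
#' @return data.frame with `score` and `category`.
#' @export
mipi_b_score <- function(age, ecog, ldh, ldh_uln, wbc, ki67,
                         constants = mipi_constants()$mipi_b) {
  if (any(ki67 < 0 | ki67 > 100)) stop_ctx("ki67 must be in [0, 100] percent")
  base <- mipi_score(age, ecog, ldh, ldh_uln, wbc, constants = constants)
  score <- base$score + constants$ki67 * ki67
  data.frame(score = score, category = score_to_category(score, constants$cut))
}

#' Radiomic-signature configuration
#'
#' Cutoffs for dichotomizing the signature features. The defaults are the
#' study cohort's ROC-derived values; note that the absolute Entropy cutoff
#' depends on the grey-level binning and entropy log base, so for other
#' cohorts the cutoffs should be recomputed with [roc_cutoff()].
#'
#' @param suvmean_cutoff default 3.55.
#' @param entropy_cutoff default 3.5.
#' @param n_categories 2 or 3.
#' @return list of class `signature_config`.
#' @export
signature_config <- function(suvmean_cutoff = 3.55, entropy_cutoff = 3.5,
                             n_categories = 3) {
  stopifnot(is.finite(suvmean_cutoff), is.finite(entropy_cutoff),
            n_categories %in% c(2, 3))
  structure(list(suvmean_cutoff = suvmean_cutoff,
                 entropy_cutoff = entropy_cutoff,
                 n_categories = n_categories),
            class = "signature_config")
}

#' Majority-vote metabolic risk from dichotomized SUVmean and Entropy
#'
#' Three-category model: "high" if both features exceed their cutoffs, "low"
#' if both are at or below, "intermediate" otherwise (same number of
#' features above and below). Two-category model: "high" if both exceed,
#' "low" otherwise (either feature at or below its cutoff). Values exactly
#' at a cutoff count as below.
#'
#' @param suv_mean,entropy feature values (vectorized).
#' @param cfg a [signature_config()].
#' @return factor with levels low < intermediate < high (3-cat) or
#'   low < high (2-cat).
#' @export
metabolic_risk <- function(suv_mean, entropy, cfg = signature_config()) {
  if (any(!is.finite(suv_mean)) || any(!is.finite(entropy)))
    stop_ctx("signature features must be finite")
  above <- (suv_mean > cfg$suvmean_cutoff) + (entropy > cfg$entropy_cutoff)
  if (cfg$n_categories == 2) {
    factor(ifelse(above == 2, "high", "low"), levels = c("low", "high"))
  } else {
    factor(c("low", "intermediate", "high")[above + 1],
           levels = c("low", "intermediate", "high"))
  }
}

#' Modify a MIPI category by metabolic risk
#'
#' High metabolic risk adds one risk level (unless already 3), low subtracts
#' one (unless already 1), intermediate leaves the category unchanged.
#'
#' @param mipi_cat integer MIPI or MIPI-b category in {1, 2, 3}.
#' @param metabolic metabolic-risk category ("low"/"intermediate"/"high").
#' @return modified integer category in {1, 2, 3}. Vectorized.
#' @export
modify_mipi <- function(mipi_cat, metabolic) {
  mipi_cat <- as.integer(mipi_cat)
  if (any(!mipi_cat %in% 1:3)) stop_ctx("mipi_cat must be 1, 2 or 3")
  metabolic <- as.character(metabolic)
  ok <- metabolic %in% c("low", "intermediate", "high")
  if (any(!ok)) stop_ctx("invalid metabolic category: ",
                         paste(unique(metabolic[!ok]), collapse = ", "))
  shift <- ifelse(metabolic == "high", 1L, ifelse(metabolic == "low", -1L, 0L))
  pmin(3L, pmax(1L, mipi_cat + shift))
}

#' Derive the 2-year progression-free-survival event flag
#'
#' Progression (or death) at or before 24 months.
#' @param pfs_months follow-up time in months.
#' @param progressed event flag.
#' @return logical vector.
#' @export
derive_pfs2y <- function(pfs_months, progressed) {
  as.logical(progressed) & pfs_months <= 24
}

#' Build per-patient risk profiles
#'
#' Joins a (harmonized) feature table with the clinical table 1:1 on
#' `patient_id` and computes MIPI, MIPI-b, metabolic risk (2- and
#' 3-category), and the metabolic-risk-modified MIPI-m and MIPI-bm.
#'
#' @param features data.frame with patient_id, suv_mean and entropy.
#' @param patients clinical table (see [generate_cohort()] for the schema).
#' @param cfg a [signature_config()] (the 3-category variant is used for the
#'   MIPI modification, per the majority-vote definition).
#' @param constants see [mipi_constants()].
#' @return data.frame, one row per patient: scores, categories, metabolic
#'   risk, modified categories, survival columns and `pfs2y_event`.
#' @export
build_risk_profiles <- function(features, patients, cfg = signature_config(),
                                constants = mipi_constants()) {
  unmatched <- c(setdiff(features$patient_id, patients$patient_id),
                 setdiff(patients$patient_id, features$patient_id))
  if (length(unmatched) > 0)
    stop_ctx("patient ids do not match 1:1: ", paste(unique(unmatched), collapse = ", "))
  if (nrow(features) == 0) stop_ctx("empty join")
  p <- patients[match(features$patient_id, patients$patient_id), ]
  m <- mipi_score(p$age, p$ecog, p$ldh, p$ldh_uln, p$wbc, constants$mipi)
  mb <- mipi_b_score(p$age, p$ecog, p$ldh, p$ldh_uln, p$wbc, p$ki67, constants$mipi_b)
  cfg3 <- signature_config(cfg$suvmean_cutoff, cfg$entropy_cutoff, 3)
  cfg2 <- signature_config(cfg$suvmean_cutoff, cfg$entropy_cutoff, 2)
  met3 <- metabolic_risk(features$suv_mean, features$entropy, cfg3)
  met2 <- metabolic_risk(features$suv_mean, features$entropy, cfg2)
  data.frame(
    patient_id = features$patient_id,
    suv_mean = features$suv_mean, entropy = features$entropy,
    mipi_score = m$score, mipi_cat = m$category,
    mipi_b_score = mb$score, mipi_b_cat = mb$category,
    metabolic_risk = met3, metabolic_risk_2cat = met2,
    mipi_m_cat = modify_mipi(m$category, met3),
    mipi_bm_cat = modify_mipi(mb$category, met3),
    pfs_months = p$pfs_months, progressed = p$progressed,
    pfs2y_event = derive_pfs2y(p$pfs_months, p$progressed),
    stringsAsFactors = FALSE)
}
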