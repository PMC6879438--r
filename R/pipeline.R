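#' Pipeline configuration
#'
#' Bundles the per-stage settings of the full analysis chain:
#' simulate -> segment -> extract -> harmonize -> signature -> risk ->
#' survival -> predict.
#'
#' @param cohort a [cohort_config()] (the synthetic input; for real cohorts
#'   supply `volumes`/`seeds`/`patients` to [run_pipeline()] instead).
#' @param threshold_fraction SUVmax fraction for segmentation (default 0.41).
#' @param connectivity 26 or 6.
#' @param n_bins grey levels for texture quantization (default 64).
#' @param distance GLCM interpixel distance (default 1).
#' @param min_pairs per-direction GLCM pair minimum (default 20).
#' @param signature signature feature names (default SUVmean + Entropy, the
#'   study's multivariate survivors).
#' @param reselect rerun univariate + forward selection on this cohort
#'   instead of using the fixed signature.
#' @param cutoffs named cutoffs for the signature features (defaults 3.55 /
#'   3.5); ignored when `recut = TRUE`.
#' @param recut recompute cutoffs on this cohort (needed for synthetic data,
#'   since absolute Entropy depends on the binning).
#' @param recut_method how to recompute: `"roc"` (Youden-optimal against the
#'   2-year PFS event, as in the study; note that outcome-derived cutoffs
#'   carry optimism that inflates downstream log-rank rejection under the
#'   null) or `"median"` (outcome-independent median dichotomization, the
#'   calibrated choice for inference on the same cohort).
#' @param do_harmonize,do_survival,do_predict stage toggles.
#' @param inject_batch apply the cohort's per-scanner feature distortions
#'   before harmonization (simulated cohorts only).
#' @param n_repeats,train_frac,hidden_neurons MLP settings.
#' @param seed master seed for all stochastic stages.
#' @param out_dir optional output directory for per-stage artifacts.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            threshold_fraction = 0.41,
                            connectivity = 26,
                            n_bins = 64, distance = 1, min_pairs = 20,
                            signature = c("suv_mean", "entropy"),
                            reselect = FALSE,
                            cutoffs = c(suv_mean = 3.55, entropy = 3.5),
                            recut = FALSE,
                            recut_method = c("roc", "median"),
                            do_harmonize = TRUE, do_survival = TRUE,
                            do_predict = TRUE, inject_batch = TRUE,
                            n_repeats = 5, train_frac = 0.70,
                            hidden_neurons = 4,
                            seed = 1, out_dir = NULL) {
  recut_method <- match.arg(recut_method)
  structure(list(cohort = cohort, threshold_fraction = threshold_fraction,
                 connectivity = connectivity, n_bins = n_bins,
                 distance = distance, min_pairs = min_pairs,
                 signature = signature, reselect = reselect,
                 cutoffs = cutoffs, recut = recut, recut_method = recut_method,
                 do_harmonize = do_harmonize, do_survival = do_survival,
                 do_predict = do_predict, inject_batch = inject_batch,
                 n_repeats = n_repeats, train_frac = train_frac,
                 hidden_neurons = hidden_neurons,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

stage_try <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop_ctx(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))))
}

#' Extract features for a whole cohort
#'
#' Segments each patient's TMTV from the seed points and extracts the full
#' radiomic feature vector.
#'
#' @param imaging per-patient list with `volume` and `seeds` (as produced by
#'   [generate_cohort()]).
#' @param scanner optional scanner label per patient, carried into the table.
#' @param cfg a [pipeline_config()] (segmentation + texture settings).
#' @return feature data.frame, one row per patient.
#' @export
extract_features_cohort <- function(imaging, scanner = NULL,
                                    cfg = pipeline_config()) {
  rows <- lapply(imaging, function(p) {
    mask <- build_tmtv(p$volume, p$seeds,
                       threshold_fraction = cfg$threshold_fraction,
                       connectivity = cfg$connectivity)
    extract_all(p$volume, mask, n_bins = cfg$n_bins,
                distance = cfg$distance, min_pairs = cfg$min_pairs)
  })
  out <- do.call(rbind, rows)
  if (!is.null(scanner)) out$scanner <- scanner
  out
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order on a simulated cohort (or supplied
#' imaging + patient tables), returning all intermediate tables and a
#' manifest. Re-running with an identical config reproduces identical
#' numeric artifacts.
#'
#' @param cfg a [pipeline_config()].
#' @param cohort optional pre-generated [generate_cohort()] result (else the
#'   config's cohort is generated).
#' @return list of class `pipeline_result`: features (raw, distorted,
#'   harmonized), selection, cutoffs, risk profiles, survival analyses,
#'   prediction results, and a manifest.
#' @export
run_pipeline <- function(cfg = pipeline_config(), cohort = NULL) {
  set.seed(cfg$seed)
  cohort <- cohort %||% stage_try("simulate", generate_cohort(cfg$cohort))
  patients <- cohort$patients

  features <- stage_try("extract",
    extract_features_cohort(cohort$imaging, scanner = patients$scanner, cfg))

  measured <- features
  if (cfg$inject_batch && !is.null(cohort$batch_map)) {
    num_cols <- setdiff(names(features), c("patient_id", "scanner"))
    measured[num_cols] <- stage_try("inject_batch",
      inject_batch_effects(features[num_cols], features$scanner, cohort$batch_map))
  }

  harmonized <- measured
  combat_model <- NULL
  if (cfg$do_harmonize) {
    num_cols <- setdiff(names(measured), c("patient_id", "scanner"))
    combat_model <- stage_try("harmonize",
      combat_fit(measured[num_cols], measured$scanner))
    harmonized[num_cols] <- stage_try("harmonize",
      combat_apply(combat_model, measured[num_cols], measured$scanner))
  }

  outcome2y <- derive_pfs2y(patients$pfs_months, patients$progressed)

  signature <- cfg$signature
  selection <- NULL
  if (cfg$reselect) {
    num_cols <- setdiff(names(harmonized), c("patient_id", "scanner"))
    uni <- lapply(num_cols, function(f)
      logistic_univariate(harmonized[[f]], outcome2y))
    sig_uni <- num_cols[vapply(uni, function(u)
      u$converged && u$p_value <= 0.05, logical(1))]
    if (length(sig_uni) > 0) {
      selection <- stage_try("select",
        forward_select(harmonized[sig_uni], outcome2y))
      if (length(selection$selected) > 0) signature <- selection$selected
    }
  }

  # the majority-vote signature uses two features; if reselection returned
  # fewer, pad with the configured defaults
  signature <- utils::head(unique(c(signature, cfg$signature)), 2)

  cuts <- cfg$cutoffs
  if (cfg$recut) {
    cuts <- vapply(signature, function(f) stage_try("recut", {
      if (cfg$recut_method == "roc")
        roc_cutoff(harmonized[[f]], outcome2y)$cutoff
      else
        stats::median(harmonized[[f]])
    }), numeric(1))
  }
  cut_for <- function(name, pos) {
    if (!is.null(names(cuts)) && name %in% names(cuts)) unname(cuts[[name]])
    else unname(cuts[[min(pos, length(cuts))]])
  }
  sig_cfg <- signature_config(
    suvmean_cutoff = cut_for(signature[1], 1),
    entropy_cutoff = cut_for(signature[2], 2), 3)
  # risk profiles use the first two signature features as (suv_mean, entropy)
  sig_feats <- data.frame(patient_id = harmonized$patient_id,
                          suv_mean = harmonized[[signature[1]]],
                          entropy = harmonized[[signature[2]]])
  risk <- stage_try("risk", build_risk_profiles(sig_feats, patients, sig_cfg))

  surv_res <- NULL
  if (cfg$do_survival) {
    surv_res <- stage_try("survival", {
      groupings <- list(
        metabolic_2cat = risk$metabolic_risk_2cat,
        metabolic_3cat = risk$metabolic_risk,
        mipi = risk$mipi_cat, mipi_b = risk$mipi_b_cat,
        mipi_m = risk$mipi_m_cat, mipi_bm = risk$mipi_bm_cat)
      lapply(groupings, function(g) {
        g <- droplevels(as.factor(g))
        km <- lapply(split(seq_len(nrow(risk)), g), function(i)
          km_estimate(risk$pfs_months[i], risk$progressed[i]))
        lr <- if (nlevels(g) >= 2 && all(table(g) > 0))
          logrank_test(risk$pfs_months, risk$progressed, g) else NULL
        cox <- if (nlevels(g) >= 2 && sum(risk$progressed) > 0)
          tryCatch(cox_hr(risk$pfs_months, risk$progressed, g),
                   error = function(e) NULL) else NULL
        list(km = km, logrank = lr, cox = cox)
      })
    })
  }

  pred <- NULL
  if (cfg$do_predict) {
    pred <- stage_try("predict",
      run_prediction_experiment(sig_feats, patients, mode = "both",
                                n_repeats = cfg$n_repeats,
                                train_frac = cfg$train_frac,
                                hidden_neurons = cfg$hidden_neurons,
                                seed = cfg$seed))
  }

  result <- list(features_raw = features, features_measured = measured,
                 features_harmonized = harmonized,
                 combat_model = combat_model,
                 signature = signature, selection = selection,
                 cutoffs = cuts, risk = risk, survival = surv_res,
                 prediction = pred, patients = patients,
                 ground_truth = cohort$ground_truth,
                 config = cfg)
  result$manifest <- write_pipeline_artifacts(result, cfg$out_dir)
  class(result) <- "pipeline_result"
  result
}

write_pipeline_artifacts <- function(result, out_dir) {
  manifest <- list(created = "run_pipeline",
                   n_patients = nrow(result$patients),
                   signature = result$signature,
                   cutoffs = as.list(result$cutoffs),
                   seed = result$config$seed,
                   artifacts = list())
  if (is.null(out_dir)) return(manifest)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- list(features_raw = result$features_raw,
               features_measured = result$features_measured,
               features_harmonized = result$features_harmonized,
               risk_profiles = result$risk,
               patients = result$patients,
               ground_truth = result$ground_truth)
  for (nm in names(tabs)) {
    if (is.null(tabs[[nm]])) next
    f <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(tabs[[nm]], f, row.names = FALSE)
    manifest$artifacts[[nm]] <- list(path = f,
                                     md5 = unname(tools::md5sum(f)))
  }
  if (!is.null(result$survival)) {
    km2 <- result$survival$metabolic_2cat$km
    km_df <- do.call(rbind, lapply(names(km2), function(g)
      cbind(group = g, as.data.frame(km2[[g]]))))
    f <- file.path(out_dir, "km_metabolic_2cat.csv")
    utils::write.csv(km_df, f, row.names = FALSE)
    manifest$artifacts$km_metabolic_2cat <- list(path = f,
                                                 md5 = unname(tools::md5sum(f)))
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result: %d patients, signature = %s>\n",
              nrow(x$patients), paste(x$signature, collapse = " + ")))
  if (!is.null(x$survival$metabolic_3cat$logrank)) {
    lr <- x$survival$metabolic_3cat$logrank
    cat(sprintf("  3-category metabolic risk log-rank: chi2 %.2f, p = %.4g\n",
                lr$statistic, lr$p_value))
  }
  if (!is.null(x$prediction)) {
    cat(sprintf("  median validation AUC: %.2f (radiomic) / %.2f (+clinical)\n",
                x$prediction$radiomic_only$summary["validation_auc", "median"],
                x$prediction$radiomic_plus_clinical$summary["validation_auc", "median"]))
  }
  invisible(x)
}
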