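#' Configuration of a synthetic PET cohort
#'
#' Defines the generative model for cohorts of multi-lesion PET volumes with
#' known ground truth: lesion geometry and uptake, spatially correlated
#' uptake heterogeneity, per-scanner feature-level batch effects, clinical
#' covariates, and progression-free-survival outcomes driven by uptake level
#' and heterogeneity.
#'
#' @param n_patients cohort size (default 107).
#' @param voxel_spacing_mm voxel size in mm (default 5.5 x 5.5 x 3.3).
#' @param grid_dim field-of-view in voxels.
#' @param lesions_per_patient integer range (default 1..3).
#' @param lesion_radius_mm lesion semi-axis range in mm (default 10..20).
#' @param suvmean_range per-patient lesion mean SUV range (default 3..6).
#' @param texture_corr_length_mm spatial-scale range of the intralesional
#'   uptake subregions in mm; short scales give many distinct subregions,
#'   i.e. heterogeneous (high-Entropy) lesions (default 4..24; `Inf` allowed
#'   for the homogeneous limit).
#' @param mosaic_amplitude relative uptake spread across subregions (default
#'   0.6: coldest ~0.7x, hottest ~1.3x the lesion mean).
#' @param noise_sd SD of the smooth residual uptake field in SUV units
#'   (default 0.1; 0 together with an infinite correlation length gives
#'   exactly constant lesions).
#' @param background_level,background_sd smooth background SUV level (~0.5-1.5).
#' @param scanner_labels batch names (default the study's five scanners).
#' @param scanner_probs batch assignment probabilities (default the study's
#'   43/41/10/10/3 patient split).
#' @param batch_shift,batch_scale per-batch additive shift and multiplicative
#'   scale applied to every feature by [inject_batch_effects()].
#' @param outcome_logit_coeffs named vector `c(intercept=, suvmean=, entropy=)`
#'   for the 2-year progression logistic model on true SUVmean and the true
#'   heterogeneity score in [0, 1]; `NULL` for a pure proportional-hazards
#'   outcome. `intercept = NA` auto-calibrates the marginal 2-year
#'   progression probability to `target_progression_2y`.
#' @param target_progression_2y marginal 2-year progression probability used
#'   for intercept calibration (default 0.372, the study's observed rate).
#' @param hazard_log_hr log hazard ratio per metabolic-risk step (default
#'   log(2.597)/2, the per-step value implied by the study's three-category
#'   high-vs-low hazard ratio).
#' @param baseline_hazard events per month in the lowest-risk group (default
#'   log(2)/39.4, a ~39-month median PFS).
#' @param censor_rate target fraction censored (default 0.2).
#' @param seed integer master seed; per-patient substreams are derived from it.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 107,
                          voxel_spacing_mm = c(5.5, 5.5, 3.3),
                          grid_dim = c(40, 40, 28),
                          lesions_per_patient = c(1, 3),
                          lesion_radius_mm = c(10, 20),
                          suvmean_range = c(3, 6),
                          texture_corr_length_mm = c(4, 24),
                          mosaic_amplitude = 0.6,
                          noise_sd = 0.1,
                          background_level = 1.0,
                          background_sd = 0.12,
                          scanner_labels = c("DSTE", "D690", "D600", "D710", "DST"),
                          scanner_probs = c(43, 41, 10, 10, 3) / 107,
                          batch_shift = c(0, 0.15, -0.15, 0.25, -0.25),
                          batch_scale = c(1, 1.05, 0.95, 1.1, 0.9),
                          outcome_logit_coeffs = c(intercept = NA,
                                                   suvmean = log(1.272),
                                                   entropy = log(5.070)),
                          target_progression_2y = 0.372,
                          hazard_log_hr = log(2.597) / 2,
                          baseline_hazard = log(2) / 39.4,
                          censor_rate = 0.2,
                          seed = 1) {
  cfg <- list(n_patients = as.integer(n_patients),
              voxel_spacing_mm = as.numeric(voxel_spacing_mm),
              grid_dim = as.integer(grid_dim),
              lesions_per_patient = as.integer(range(lesions_per_patient)),
              lesion_radius_mm = as.numeric(range(lesion_radius_mm)),
              suvmean_range = as.numeric(range(suvmean_range)),
              texture_corr_length_mm = as.numeric(range(texture_corr_length_mm)),
              mosaic_amplitude = mosaic_amplitude,
              noise_sd = noise_sd, background_level = background_level,
              background_sd = background_sd,
              scanner_labels = scanner_labels, scanner_probs = scanner_probs,
              batch_shift = batch_shift, batch_scale = batch_scale,
              outcome_logit_coeffs = outcome_logit_coeffs,
              target_progression_2y = target_progression_2y,
              hazard_log_hr = hazard_log_hr,
              baseline_hazard = baseline_hazard,
              censor_rate = censor_rate, seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  stopifnot(cfg$n_patients >= 1,
            all(cfg$voxel_spacing_mm > 0), all(cfg$grid_dim >= 4),
            all(cfg$lesions_per_patient >= 1),
            all(cfg$lesion_radius_mm > 0),
            all(cfg$suvmean_range > 0),
            all(cfg$texture_corr_length_mm > 0),
            cfg$mosaic_amplitude >= 0, cfg$mosaic_amplitude < 1,
            cfg$noise_sd >= 0, cfg$background_sd >= 0,
            length(cfg$scanner_labels) == length(cfg$scanner_probs),
            length(cfg$batch_shift) == length(cfg$scanner_labels),
            length(cfg$batch_scale) == length(cfg$scanner_labels),
            all(cfg$batch_scale > 0),
            abs(sum(cfg$scanner_probs) - 1) < 1e-8,
            cfg$baseline_hazard > 0,
            cfg$censor_rate >= 0, cfg$censor_rate < 1,
            cfg$target_progression_2y > 0, cfg$target_progression_2y < 1)
  # largest lesion (plus placement margin) must fit inside the field of view
  rv <- max(cfg$lesion_radius_mm) / cfg$voxel_spacing_mm
  if (any(2 * (ceiling(rv) + 1) + 1 > cfg$grid_dim))
    stop_ctx("lesion radius too large for the field of view")
  invisible(cfg)
}

# Per-patient reproducible substream (independent of patient order)
patient_seed <- function(cfg, patient_index) {
  (cfg$seed * 48271 + patient_index * 10007) %% 2147483647L
}

# Largest-remainder apportionment of n into groups with given proportions
apportion_counts <- function(n, probs) {
  raw <- n * probs / sum(probs)
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

runif_range <- function(n, r) {
  if (r[1] == r[2]) return(rep(r[1], n))  # degenerate range (incl. Inf)
  stats::runif(n, r[1], r[2])
}

#' Generate one patient's lesion volume with ground truth
#'
#' A smooth background (SUV ~ 0.5-1.5) with ellipsoidal lesions whose
#' interior uptake is a subregion mosaic: a spatially correlated field at
#' the patient's correlation length is sliced into equal-probability
#' plateaus of distinct uptake (one level per metabolic subregion), plus a
#' smooth residual field of SD `noise_sd`. The number of plateau levels
#' grows as the subregion scale shrinks relative to the lesion diameter,
#' so short correlation lengths give heterogeneous, high-Entropy lesions
#' and scales at or beyond the lesion diameter give a single level. Seeds
#' (hottest lesion voxels) and the true lesion mask are returned alongside
#' the volume.
#'
#' @param config a [cohort_config()].
#' @param patient_index 1-based patient number (selects the RNG substream).
#' @return list with `volume` ([pet_volume()]), `true_mask` (logical array),
#'   `seeds` (matrix of 1-based voxel indices), and `params` (per-patient
#'   true SUVmean, correlation length, heterogeneity score, lesion count).
#' @export
generate_lesion_volume <- function(config, patient_index = 1) {
  validate_cohort_config(config)
  set.seed(patient_seed(config, patient_index))
  dm <- config$grid_dim
  sp <- config$voxel_spacing_mm
  suvmean <- runif_range(1, config$suvmean_range)
  corr_len <- runif_range(1, config$texture_corr_length_mm)
  n_les <- if (config$lesions_per_patient[1] == config$lesions_per_patient[2])
    config$lesions_per_patient[1]
  else sample(config$lesions_per_patient[1]:config$lesions_per_patient[2], 1)

  bg <- config$background_level +
    config$background_sd * gaussian_random_field(dm, sp, 20)
  vol <- pmin(pmax(bg, 0.5), 1.5)
  true_mask <- array(FALSE, dm)
  seeds <- matrix(0L, n_les, 3, dimnames = list(NULL, c("x", "y", "z")))

  for (l in seq_len(n_les)) {
    radii_mm <- runif_range(3, config$lesion_radius_mm)
    rv <- radii_mm / sp                       # semi-axes in voxels
    margin <- ceiling(rv) + 1
    ctr <- vapply(1:3, function(a)
      sample(seq(margin[a], dm[a] - margin[a]), 1), numeric(1))
    lo <- pmax(1, floor(ctr - rv)); hi <- pmin(dm, ceiling(ctr + rv))
    bx <- lo[1]:hi[1]; by <- lo[2]:hi[2]; bz <- lo[3]:hi[3]
    d2 <- outer(outer(((bx - ctr[1]) / rv[1])^2, ((by - ctr[2]) / rv[2])^2, "+"),
                ((bz - ctr[3]) / rv[3])^2, "+")
    inside <- d2 <= 1
    if (!any(inside)) inside[which.min(d2)] <- TRUE
    bdm <- dim(inside)
    # subregion mosaic: number of plateau levels ~ lesion diameter over the
    # subregion scale, capped at 8; a scale >= the diameter gives one level
    diameter <- 2 * mean(radii_mm)
    k <- if (is.infinite(corr_len)) 1L
      else 1L + min(7L, as.integer(floor(diameter / corr_len)))
    if (k > 1) {
      W <- gaussian_random_field(bdm, sp, corr_len)
      lev <- cut(stats::pnorm(W), breaks = seq(0, 1, length.out = k + 1),
                 labels = FALSE, include.lowest = TRUE)
      mosaic <- array((lev - (k + 1) / 2) / (k - 1), bdm)
    } else {
      mosaic <- array(0, bdm)
    }
    resid <- if (config$noise_sd > 0)
      config$noise_sd * gaussian_random_field(bdm, sp, 12) else array(0, bdm)
    uptake <- suvmean * (1 + config$mosaic_amplitude * mosaic) + resid
    sub <- vol[bx, by, bz, drop = FALSE]
    sub[inside] <- pmax(uptake[inside], 0.1)
    vol[bx, by, bz] <- sub
    msub <- true_mask[bx, by, bz, drop = FALSE]
    msub[inside] <- TRUE
    true_mask[bx, by, bz] <- msub
    # seed: hottest voxel of this lesion
    les_vals <- ifelse(inside, sub, -Inf)
    w <- which(les_vals == max(les_vals), arr.ind = TRUE)[1, ]
    seeds[l, ] <- as.integer(c(bx[w[1]], by[w[2]], bz[w[3]]))
  }
  het <- heterogeneity_score(config, corr_len)
  list(volume = pet_volume(vol, sp, sprintf("P%03d", patient_index)),
       true_mask = true_mask, seeds = seeds,
       params = list(suvmean = suvmean, corr_length_mm = corr_len,
                     heterogeneity = het, n_lesions = n_les))
}

# True heterogeneity in [0, 1]: 1 at the shortest configured subregion
# scale (most heterogeneous), 0 at the longest or infinite.
heterogeneity_score <- function(config, corr_len) {
  r <- config$texture_corr_length_mm
  if (is.infinite(corr_len)) return(0)
  if (r[2] - r[1] <= 0) return(0.5)
  min(1, max(0, (r[2] - corr_len) / (r[2] - r[1])))
}

outcome_coeffs <- function(config) {
  co <- config$outcome_logit_coeffs
  if (is.null(co)) return(NULL)
  co <- co[c("intercept", "suvmean", "entropy")]
  if (is.na(co["intercept"])) {
    # calibrate the marginal 2-year progression probability at the
    # midpoint covariates (logit approximately linear near the target)
    mid_suv <- mean(config$suvmean_range)
    co["intercept"] <- stats::qlogis(config$target_progression_2y) -
      co["suvmean"] * mid_suv - co["entropy"] * 0.5
  }
  co
}

#' Generate a full synthetic cohort
#'
#' Draws clinical covariates (age ~ N(64.5, 10.8); ECOG categorical with
#' ~6.5% at >= 2; WBC and LDH log-normal; Ki-67 beta-scaled; Ann Arbor stage
#' and blastoid flags at the study's frequencies), assigns scanner batches,
#' generates lesion volumes (optional), and samples outcomes: event times
#' are exponential with hazard `baseline_hazard * exp(hazard_log_hr * step)`
#' where `step` in 0..2 counts which of true SUVmean / heterogeneity exceed
#' their range midpoints; when `outcome_logit_coeffs` is set, the time is
#' drawn conditional on a 2-year progression Bernoulli from the logistic
#' model, so that P(event <= 24 months) equals the logistic probability
#' exactly. Censoring is independent exponential tuned to `censor_rate`.
#'
#' @param config a [cohort_config()].
#' @param volumes generate PET volumes (`TRUE`, default) or only tables.
#' @return list with `imaging` (per-patient list of volume/seeds/true mask;
#'   `NULL` when `volumes = FALSE`), `patients` (clinical table),
#'   `ground_truth` (true per-patient generative quantities) and
#'   `batch_map` (per-scanner shift/scale for [inject_batch_effects()]).
#' @export
generate_cohort <- function(config, volumes = TRUE) {
  validate_cohort_config(config)
  n <- config$n_patients
  imaging <- NULL
  params <- vector("list", n)
  if (volumes) {
    imaging <- lapply(seq_len(n), function(i) generate_lesion_volume(config, i))
    params <- lapply(imaging, `[[`, "params")
  } else {
    for (i in seq_len(n)) {
      set.seed(patient_seed(config, i))
      suvmean <- runif_range(1, config$suvmean_range)
      corr_len <- runif_range(1, config$texture_corr_length_mm)
      params[[i]] <- list(suvmean = suvmean, corr_length_mm = corr_len,
                          heterogeneity = heterogeneity_score(config, corr_len),
                          n_lesions = NA_integer_)
    }
  }
  suv_true <- vapply(params, `[[`, numeric(1), "suvmean")
  het_true <- vapply(params, `[[`, numeric(1), "heterogeneity")

  set.seed((config$seed * 69621 + 11) %% 2147483647L)
  pid <- sprintf("P%03d", seq_len(n))
  # exactly proportional batch sizes (largest-remainder), shuffled across
  # patients: mirrors the study's fixed per-scanner counts and keeps every
  # batch large enough to harmonize
  scanner <- sample(rep(config$scanner_labels,
                        apportion_counts(n, config$scanner_probs)))
  age <- pmax(20, stats::rnorm(n, 64.5, 10.8))
  ecog <- sample(0:2, n, replace = TRUE, prob = c(0.60, 0.335, 0.065))
  wbc <- stats::rlnorm(n, log(7), 0.4)        # 10^9/L
  ldh <- stats::rlnorm(n, log(200), 0.35)     # U/L
  ldh_uln <- rep(240, n)
  ki67 <- 100 * stats::rbeta(n, 2, 3)         # %
  ann_arbor <- sample(1:4, n, replace = TRUE, prob = c(0.047, 0.121, 0.215, 0.617))
  blastoid <- stats::runif(n) < 0.187

  # outcome models
  step <- (suv_true > mean(config$suvmean_range)) + (het_true > 0.5)
  lambda <- config$baseline_hazard * exp(config$hazard_log_hr * step)
  co <- outcome_coeffs(config)
  if (is.null(co)) {
    t_event <- stats::rexp(n, rate = lambda)
    lp <- config$hazard_log_hr * step
  } else {
    lp <- co["intercept"] + co["suvmean"] * suv_true + co["entropy"] * het_true
    p2y <- stats::plogis(lp)
    b <- stats::runif(n) < p2y
    u <- stats::runif(n)
    p24 <- 1 - exp(-24 * lambda)
    # exponential conditioned on T <= 24 (progressors) or T > 24 (others)
    t_event <- ifelse(b,
                      -log(1 - u * p24) / lambda,
                      24 + stats::rexp(n, rate = lambda))
  }
  if (config$censor_rate > 0) {
    mu <- config$baseline_hazard * config$censor_rate / (1 - config$censor_rate)
    c_time <- stats::rexp(n, rate = mu)
  } else {
    c_time <- rep(Inf, n)
  }
  progressed <- t_event <= c_time
  pfs <- pmin(t_event, c_time)

  patients <- data.frame(
    patient_id = pid, age = age, ecog = ecog, wbc = wbc, ldh = ldh,
    ldh_uln = ldh_uln, ki67 = ki67, ann_arbor = ann_arbor,
    blastoid = blastoid, scanner = scanner,
    pfs_months = pfs, progressed = progressed,
    stringsAsFactors = FALSE)
  ground_truth <- data.frame(
    patient_id = pid, scanner = scanner,
    true_suvmean = suv_true, true_heterogeneity = het_true,
    true_corr_length_mm = vapply(params, `[[`, numeric(1), "corr_length_mm"),
    true_risk_step = step, true_linear_predictor = as.numeric(lp),
    true_event_time = t_event,
    stringsAsFactors = FALSE)
  batch_map <- data.frame(batch = config$scanner_labels,
                          shift = config$batch_shift,
                          scale = config$batch_scale,
                          stringsAsFactors = FALSE)
  list(imaging = imaging, patients = patients,
       ground_truth = ground_truth, batch_map = batch_map)
}

#' Inject per-batch location/scale distortions into a feature table
#'
#' Emulates scanner-dependent technical differences at the feature level
#' (where ComBat harmonization operates): each feature value x in batch b
#' becomes `scale_b * x + shift_b`.
#'
#' @param features data.frame of numeric features (non-numeric columns such
#'   as patient_id/scanner pass through untouched).
#' @param batch character vector of batch labels, one per row.
#' @param batch_map data.frame with columns batch, shift, scale.
#' @return distorted feature table, same shape and order.
#' @export
inject_batch_effects <- function(features, batch, batch_map) {
  unknown <- setdiff(unique(batch), batch_map$batch)
  if (length(unknown) > 0)
    stop_ctx("unknown batch label(s): ", paste(unknown, collapse = ", "))
  i <- match(batch, batch_map$batch)
  num <- vapply(features, is.numeric, logical(1))
  out <- features
  out[num] <- lapply(features[num],
                     function(x) batch_map$scale[i] * x + batch_map$shift[i])
  out
}

#' Write a generated cohort to disk
#'
#' One NIfTI volume per patient, a 0-based seed CSV, the patient table and
#' the ground-truth table.
#'
#' @param cohort result of [generate_cohort()] (with volumes).
#' @param dir output directory (created if needed).
#' @return invisible vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  if (is.null(cohort$imaging)) stop_ctx("cohort was generated without volumes")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  seed_rows <- list()
  for (p in cohort$imaging) {
    f <- file.path(dir, paste0(p$volume$patient_id, ".nii.gz"))
    write_volume(p$volume, f)
    paths <- c(paths, f)
    seed_rows[[length(seed_rows) + 1]] <- data.frame(
      patient_id = p$volume$patient_id,
      x = p$seeds[, 1] - 1L, y = p$seeds[, 2] - 1L, z = p$seeds[, 3] - 1L)
  }
  seeds_path <- file.path(dir, "seeds.csv")
  utils::write.csv(do.call(rbind, seed_rows), seeds_path, row.names = FALSE)
  pat_path <- file.path(dir, "patients.csv")
  utils::write.csv(cohort$patients, pat_path, row.names = FALSE)
  gt_path <- file.path(dir, "ground_truth.csv")
  utils::write.csv(cohort$ground_truth, gt_path, row.names = FALSE)
  invisible(c(paths, seeds_path, pat_path, gt_path))
}
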