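test_that("correlations recover exact limits and tie-corrected tau-b", {
  x <- c(1, 3, 4, 7, 9, 12)
  expect_equal(correlate(x, 2 * x + 1, "pearson")$coefficient, 1)
  expect_equal(correlate(x, exp(x / 5), "kendall")$coefficient, 1)
  # ties: tau-b against the exhaustive pair-count formula
  xt <- c(1, 2, 2, 3); yt <- c(1, 1, 2, 2)
  expect_equal(correlate(xt, yt, "kendall")$coefficient,
               taub_oracle(xt, yt), tolerance = 1e-12)
  set.seed(6)
  for (r in 1:5) {
    a <- sample(1:5, 25, replace = TRUE)
    b <- sample(1:4, 25, replace = TRUE)
    expect_equal(correlate(a, b, "kendall")$coefficient,
                 taub_oracle(a, b), tolerance = 1e-12)
  }
  expect_error(correlate(rep(1, 5), 1:5), "zero variance")
})

test_that("univariate logistic regression matches grid-search MLE", {
  set.seed(19)
  for (r in 1:10) {
    n <- sample(40:200, 1)
    x <- rnorm(n)
    y <- rbinom(n, 1, plogis(-0.3 + 0.8 * x))
    if (length(unique(y)) < 2) next
    fit <- logistic_univariate(x, y)
    if (!fit$converged) next
    mle <- grid_logistic(x, y)
    expect_lt(abs(fit$coefficient - mle[2]), 1e-3)
  }
})

test_that("logistic preconditions and separation are handled", {
  expect_error(logistic_univariate(rnorm(30), rep(0, 30)), "single class")
  expect_error(logistic_univariate(rnorm(5), c(0, 1, 0, 1, 0)), "n >= 10")
  x <- c(rnorm(20, -8), rnorm(20, 8))
  y <- rep(c(0, 1), each = 20)          # complete separation
  fit <- logistic_univariate(x, y)
  expect_false(fit$converged)
})

test_that("a simulated odds ratio of 1.272 per unit is recovered", {
  set.seed(23)
  n <- 5000
  x <- rnorm(n, 4, 2)
  y <- rbinom(n, 1, plogis(-1.5 + log(1.272) * x))
  fit <- logistic_univariate(x, y)
  expect_true(fit$or > 1.2 && fit$or < 1.35)
  expect_lt(fit$p_value, 0.05)
})

test_that("forward selection keeps signal and respects the entry threshold", {
  set.seed(29)
  signal_first <- 0
  exact <- 0
  for (r in 1:50) {
    n <- 500
    X <- data.frame(signal = rnorm(n), n1 = rnorm(n), n2 = rnorm(n),
                    n3 = rnorm(n), n4 = rnorm(n), n5 = rnorm(n))
    y <- rbinom(n, 1, plogis(-0.4 + 1.0 * X$signal))
    sel <- forward_select(X, y)
    if (length(sel$selected) > 0 && sel$selected[1] == "signal")
      signal_first <- signal_first + 1
    if (identical(sel$selected, "signal")) exact <- exact + 1
    if (nrow(sel$steps) > 0) expect_true(all(sel$steps$p_value <= 0.05))
  }
  expect_gte(signal_first / 50, 0.9)
  # with five independent noise candidates, the chance that none slips in
  # after the signal is about 0.95^5 = 0.77
  expect_gt(exact / 50, 0.6)
})

test_that("pure-noise candidates enter at about the nominal rate", {
  set.seed(37)
  empty <- 0
  for (r in 1:100) {
    x <- data.frame(noise = rnorm(120))
    y <- rbinom(120, 1, 0.4)
    if (length(unique(y)) < 2) { empty <- empty + 1; next }
    sel <- forward_select(x, y)
    if (length(sel$selected) == 0) empty <- empty + 1
  }
  expect_gte(empty / 100, 0.85)   # per-candidate type-I error ~5%
})

test_that("only one of two duplicated features enters", {
  set.seed(43)
  n <- 400
  a <- rnorm(n)
  X <- data.frame(dup1 = a, dup2 = a, other = rnorm(n))
  y <- rbinom(n, 1, plogis(1.2 * a))
  sel <- forward_select(X, y)
  expect_equal(sum(c("dup1", "dup2") %in% sel$selected), 1)
  expect_equal(sel$selected[1], "dup1")   # tie broken by column order
})

test_that("MLP separates well-separated classes and reports 5 stratified splits", {
  set.seed(47)
  n <- 300
  y <- rep(c(0, 1), each = n / 2)
  X <- data.frame(f1 = rnorm(n, y * 4), f2 = rnorm(n, -y * 3))
  res <- mlp_predict_2ypfs(X, y, n_repeats = 5, seed = 101)
  expect_equal(nrow(res$runs), 5)
  expect_gte(res$summary["validation_auc", "median"], 0.95)
  # split sizes 70/30 +- 1 subject
  expect_true(all(abs(res$runs$n_train - 0.7 * n) <= 1))
  expect_true(all(res$runs$n_train + res$runs$n_validation == n))
  # both classes in every training split
  for (s in res$splits)
    expect_equal(length(unique(y[s$train])), 2)
})

test_that("MLP validation AUC is near chance under label permutation", {
  set.seed(53)
  n <- 300
  y <- rep(c(0, 1), each = n / 2)
  X <- data.frame(f1 = rnorm(n, y * 4), f2 = rnorm(n, -y * 3))
  y_perm <- sample(y)
  res <- mlp_predict_2ypfs(X, y_perm, n_repeats = 5, seed = 59)
  auc <- res$summary["validation_auc", "median"]
  expect_true(auc > 0.4 && auc < 0.6)
})

test_that("clinical variables with real signal raise the prediction AUC", {
  set.seed(61)
  n <- 240
  diffs <- vapply(1:10, function(s) {
    lin_rad <- rnorm(n, 0, 0.6)
    clin_sig <- rnorm(n)
    y <- rbinom(n, 1, plogis(lin_rad + 1.5 * clin_sig))
    feats <- data.frame(patient_id = paste0("P", 1:n),
                        suv_mean = lin_rad + rnorm(n, 0, 0.2),
                        entropy = rnorm(n))
    pats <- data.frame(patient_id = paste0("P", 1:n),
                       ecog = clin_sig,           # clinical variables carry
                       wbc = exp(clin_sig / 2),   # the independent signal
                       ldh = 200 + 40 * clin_sig, ki67 = 50,
                       pfs_months = ifelse(y == 1, 12, 40),
                       progressed = y == 1)
    both <- run_prediction_experiment(feats, pats, mode = "both",
                                      n_repeats = 3, seed = 70 + s)
    both$radiomic_plus_clinical$summary["validation_auc", "median"] -
      both$radiomic_only$summary["validation_auc", "median"]
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("prediction experiment is deterministic given the master seed", {
  set.seed(67)
  n <- 120
  y <- rbinom(n, 1, 0.4)
  feats <- data.frame(patient_id = paste0("P", 1:n),
                      suv_mean = rnorm(n, 4), entropy = rnorm(n, 3.5))
  pats <- data.frame(patient_id = paste0("P", 1:n),
                     ecog = sample(0:2, n, TRUE), wbc = rlnorm(n, 2),
                     ldh = rlnorm(n, 5), ki67 = runif(n, 0, 100),
                     pfs_months = ifelse(y == 1, 10, 40), progressed = y == 1)
  r1 <- run_prediction_experiment(feats, pats, mode = "radiomic_only",
                                  n_repeats = 3, seed = 5)
  r2 <- run_prediction_experiment(feats, pats, mode = "radiomic_only",
                                  n_repeats = 3, seed = 5)
  expect_identical(r1$runs, r2$runs)
})

test_that("univariate screening flags both true signature features", {
  set.seed(71)
  flagged <- 0
  for (r in 1:50) {
    cfg <- cohort_config(n_patients = 500, seed = 7000 + r, censor_rate = 0,
                         outcome_logit_coeffs = c(intercept = NA,
                                                  suvmean = log(1.5),
                                                  entropy = log(8)))
    co <- generate_cohort(cfg, volumes = FALSE)
    y <- co$ground_truth$true_event_time <= 24
    p_suv <- logistic_univariate(co$ground_truth$true_suvmean, y)$p_value
    p_het <- logistic_univariate(co$ground_truth$true_heterogeneity, y)$p_value
    if (p_suv <= 0.05 && p_het <= 0.05) flagged <- flagged + 1
  }
  expect_gte(flagged / 50, 0.8)
})
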