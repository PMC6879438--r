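#' Correlation between a feature and an outcome
#'
#' Pearson (t-approximation p-value) or Kendall tau-b (tie-corrected, normal
#' approximation under ties), as used to relate radiomic features to PFS and
#' 2-year PFS status.
#'
#' @param x,y numeric vectors (length >= 3).
#' @param method "pearson" or "kendall" (tau-b).
#' @return list with `coefficient` and `p_value`.
#' @export
correlate <- function(x, y, method = c("pearson", "kendall")) {
  method <- match.arg(method)
  if (length(x) != length(y) || length(x) < 3) stop_ctx("need equal lengths >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop_ctx("zero variance")
  ct <- suppressWarnings(stats::cor.test(x, y, method = method, exact = FALSE))
  list(coefficient = unname(ct$estimate), p_value = ct$p.value)
}

#' Univariate binary logistic regression for one feature
#'
#' Maximum-likelihood fit (intercept + slope); reports the odds ratio per
#' unit of the feature with a Wald 95% CI and p-value. Complete or
#' quasi-complete separation is flagged (`converged = FALSE`) rather than
#' reported as a silent estimate.
#'
#' @param feature numeric predictor.
#' @param outcome binary outcome (both classes required, n >= 10).
#' @return list of class `logistic_fit`: coefficient, or, ci, p_value,
#'   log_likelihood, converged.
#' @export
logistic_univariate <- function(feature, outcome) {
  outcome <- as.integer(as.logical(outcome))
  if (length(feature) != length(outcome)) stop_ctx("lengths differ")
  if (length(outcome) < 10) stop_ctx("need n >= 10")
  if (length(unique(outcome)) < 2) stop_ctx("outcome has a single class")
  sep_flag <- FALSE
  fit <- withCallingHandlers(
    stats::glm(outcome ~ feature, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_flag <<- TRUE
      invokeRestart("muffleWarning")
    })
  co <- summary(fit)$coefficients
  beta <- co["feature", "Estimate"]
  se <- co["feature", "Std. Error"]
  converged <- fit$converged && !sep_flag && se < 50
  structure(list(coefficient = beta,
                 or = exp(beta),
                 ci = exp(beta + c(-1, 1) * stats::qnorm(0.975) * se),
                 p_value = co["feature", "Pr(>|z|)"],
                 log_likelihood = as.numeric(stats::logLik(fit)),
                 converged = converged),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic: OR %.3f (95%% CI %.3f-%.3f), p = %.4g%s>\n",
              x$or, x$ci[1], x$ci[2], x$p_value,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Forward selection of logistic predictors by likelihood ratio
#'
#' Starts from the intercept-only model; at each step adds the candidate
#' with the smallest likelihood-ratio p-value if it is at or below
#' `entry_p`, and stops when no remaining candidate qualifies. Ties are
#' broken by smallest p, then column order.
#'
#' @param candidates data.frame/matrix of candidate features.
#' @param outcome binary outcome.
#' @param entry_p entry threshold (default 0.05).
#' @return list of class `selection_result`: `selected` (ordered names),
#'   `steps` (per-step LR statistic and p), `final_fit` (glm object).
#' @export
forward_select <- function(candidates, outcome, entry_p = 0.05) {
  X <- as.data.frame(candidates)
  if (ncol(X) < 1) stop_ctx("need >= 1 candidate")
  outcome <- as.integer(as.logical(outcome))
  selected <- character(0)
  steps <- list()
  repeat {
    remaining <- setdiff(names(X), selected)
    if (length(remaining) == 0) break
    base_formula <- if (length(selected) == 0) "y ~ 1"
      else paste("y ~", paste(selected, collapse = " + "))
    dat <- cbind(data.frame(y = outcome), X)
    base_fit <- stats::glm(stats::as.formula(base_formula), stats::binomial(), dat)
    stats_p <- vapply(remaining, function(f) {
      fit <- stats::glm(stats::as.formula(paste(base_formula, "+", f)),
                        stats::binomial(), dat)
      lr <- as.numeric(2 * (stats::logLik(fit) - stats::logLik(base_fit)))
      c(lr, stats::pchisq(lr, df = 1, lower.tail = FALSE))
    }, numeric(2))
    best <- which.min(stats_p[2, ])   # ties: first in column order
    if (stats_p[2, best] > entry_p) break
    selected <- c(selected, remaining[best])
    steps[[length(steps) + 1]] <- data.frame(
      feature = remaining[best],
      lr_statistic = stats_p[1, best], p_value = stats_p[2, best])
  }
  dat <- cbind(data.frame(y = outcome), X)
  final_formula <- if (length(selected) == 0) "y ~ 1"
    else paste("y ~", paste(selected, collapse = " + "))
  structure(list(selected = selected,
                 steps = if (length(steps)) do.call(rbind, steps)
                   else data.frame(feature = character(0),
                                   lr_statistic = numeric(0),
                                   p_value = numeric(0)),
                 final_fit = stats::glm(stats::as.formula(final_formula),
                                        stats::binomial(), dat)),
            class = "selection_result")
}

stratified_split <- function(outcome, train_frac, max_tries = 100) {
  n <- length(outcome)
  for (t in seq_len(max_tries)) {
    idx <- unlist(lapply(split(seq_len(n), outcome), function(g) {
      k <- round(train_frac * length(g))
      k <- max(1, min(length(g) - 1, k))
      sample(g, k)
    }), use.names = FALSE)
    train <- sort(idx)
    if (length(unique(outcome[train])) == 2 &&
        length(unique(outcome[-train])) == 2) return(train)
  }
  stop_ctx("could not build a split with both classes after ", max_tries, " attempts")
}

#' MLP prediction of 2-year PFS with repeated random splits
#'
#' Repeats `n_repeats` times: draws a fresh random 70/30 train/validation
#' split (stratified by outcome), standardizes inputs on the training split
#' only, trains a single-hidden-layer feed-forward network with softmax
#' output (`nnet`), and evaluates validation AUC plus train/validation
#' accuracy at probability 0.5. Reported as per-repetition rows plus
#' median-and-range summaries.
#'
#' @param features data.frame/matrix of numeric inputs.
#' @param outcome binary outcome (n >= 20, both classes).
#' @param n_repeats number of repetitions (default 5).
#' @param train_frac training fraction (default 0.70).
#' @param hidden_neurons hidden-layer width (default 4, minimum 3).
#' @param seed RNG seed for splits and initial weights.
#' @param maxit,decay nnet training controls.
#' @return list of class `mlp_result`: `runs` (per-repetition metrics),
#'   `summary` (median and range of each metric), `splits`.
#' @export
mlp_predict_2ypfs <- function(features, outcome, n_repeats = 5,
                              train_frac = 0.70, hidden_neurons = 4,
                              seed = 1, maxit = 500, decay = 1e-3) {
  X <- as.matrix(features)
  y <- as.integer(as.logical(outcome))
  if (nrow(X) < 20) stop_ctx("need >= 20 subjects")
  if (length(unique(y)) < 2) stop_ctx("outcome has a single class")
  if (hidden_neurons < 3) stop_ctx("hidden_neurons must be >= 3")
  set.seed(seed)
  runs <- vector("list", n_repeats)
  splits <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    train <- stratified_split(y, train_frac)
    mu <- colMeans(X[train, , drop = FALSE])
    sdv <- apply(X[train, , drop = FALSE], 2, stats::sd)
    sdv[sdv == 0] <- 1
    Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
    tgt <- cbind(1 - y, y)
    fit <- nnet::nnet(Z[train, , drop = FALSE], tgt[train, ],
                      size = hidden_neurons, softmax = TRUE,
                      maxit = maxit, decay = decay, trace = FALSE)
    prob <- stats::predict(fit, Z)[, 2]
    val <- setdiff(seq_len(nrow(X)), train)
    runs[[r]] <- data.frame(
      repetition = r,
      n_train = length(train), n_validation = length(val),
      validation_auc = auc_rank(prob[val], y[val]),
      train_accuracy = mean((prob[train] > 0.5) == (y[train] == 1)),
      validation_accuracy = mean((prob[val] > 0.5) == (y[val] == 1)))
    splits[[r]] <- list(train = train, validation = val)
  }
  runs <- do.call(rbind, runs)
  summarize <- function(v) c(median = stats::median(v), min = min(v), max = max(v))
  structure(list(runs = runs,
                 summary = rbind(validation_auc = summarize(runs$validation_auc),
                                 train_accuracy = summarize(runs$train_accuracy),
                                 validation_accuracy = summarize(runs$validation_accuracy)),
                 splits = splits),
            class = "mlp_result")
}

#' @export
print.mlp_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<mlp_result: %d repetitions; validation AUC %.2f-%.2f (median %.2f)>\n",
              nrow(x$runs), s["validation_auc", "min"],
              s["validation_auc", "max"], s["validation_auc", "median"]))
  invisible(x)
}

#' Run the 2-year PFS prediction experiment
#'
#' Assembles the inputs (the radiomic signature SUVmean + Entropy, optionally
#' plus ECOG, WBC, LDH and Ki-67) and runs [mlp_predict_2ypfs()].
#'
#' @param features feature table with patient_id, suv_mean, entropy.
#' @param patients clinical table with ecog, wbc, ldh, ki67, pfs_months,
#'   progressed.
#' @param mode "radiomic_only", "radiomic_plus_clinical", or "both".
#' @param ... passed to [mlp_predict_2ypfs()].
#' @return an `mlp_result`, or a named list of two when `mode = "both"`.
#' @export
run_prediction_experiment <- function(features, patients,
                                      mode = c("both", "radiomic_only",
                                               "radiomic_plus_clinical"),
                                      ...) {
  mode <- match.arg(mode)
  p <- patients[match(features$patient_id, patients$patient_id), ]
  outcome <- derive_pfs2y(p$pfs_months, p$progressed)
  rad <- data.frame(suv_mean = features$suv_mean, entropy = features$entropy)
  clin <- cbind(rad, data.frame(ecog = p$ecog, wbc = p$wbc,
                                ldh = p$ldh, ki67 = p$ki67))
  if (mode == "radiomic_only") return(mlp_predict_2ypfs(rad, outcome, ...))
  if (mode == "radiomic_plus_clinical") return(mlp_predict_2ypfs(clin, outcome, ...))
  list(radiomic_only = mlp_predict_2ypfs(rad, outcome, ...),
       radiomic_plus_clinical = mlp_predict_2ypfs(clin, outcome, ...))
}
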