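#' Kaplan-Meier product-limit estimate
#'
#' Wraps `survival::survfit` (which processes events before censorings at
#' tied times, the convention adopted here). The median is the smallest
#' event time with S(t) <= 0.5, `NA` if the curve never reaches 0.5.
#'
#' @param times follow-up times (months), >= 0.
#' @param events event indicators (TRUE/1 = progression or death).
#' @return object of class `km_curve`: `time`, `surv`, `n_risk`, `n_event`,
#'   `median`.
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0) stop_ctx("empty input")
  if (length(times) != length(events)) stop_ctx("times and events differ in length")
  if (any(times < 0)) stop_ctx("negative times")
  fit <- survival::survfit(survival::Surv(times, as.integer(events)) ~ 1)
  med <- {
    i <- which(fit$surv <= 0.5 & fit$n.event > 0)
    if (length(i) == 0) NA_real_ else min(fit$time[i])
  }
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event, median = med, n = length(times)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve: n=%d, %d event(s), median %s months>\n",
              x$n, sum(x$n_event),
              if (is.na(x$median)) "not reached" else format(x$median)))
  invisible(x)
}

#' Export a KM curve as a data.frame
#' @param x a `km_curve`.
#' @param ... unused.
#' @return data.frame (time, survival, n_risk, n_event).
#' @export
as.data.frame.km_curve <- function(x, ...) {
  data.frame(time = x$time, survival = x$surv,
             n_risk = x$n_risk, n_event = x$n_event)
}

#' Log-rank test for group differences in survival
#'
#' Standard observed-minus-expected chi-square over distinct event times
#' (`survival::survdiff`, rho = 0), with k - 1 degrees of freedom.
#'
#' @param times,events as in [km_estimate()].
#' @param group group labels (>= 2 groups).
#' @return list of class `logrank_result`: `statistic`, `df`, `p_value`.
#' @export
logrank_test <- function(times, events, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2) stop_ctx("log-rank needs >= 2 groups")
  sd <- survival::survdiff(survival::Surv(times, as.integer(events)) ~ group)
  df <- length(sd$n) - 1
  structure(list(statistic = as.numeric(sd$chisq), df = df,
                 p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE)),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("<log-rank: chi-square %.3f on %d df, p = %.4g>\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Cox proportional-hazards ratios vs a reference group
#'
#' Univariate Cox fit on group indicators (Breslow tie handling), returning
#' the hazard ratio of each group against the reference with Wald 95%
#' confidence intervals and p-values.
#'
#' @param times,events as in [km_estimate()].
#' @param group group labels.
#' @param reference reference level (default: first sorted level).
#' @return data.frame of class `cox_result`: group, hr, lower, upper,
#'   p_value, with attribute `converged`.
#' @export
cox_hr <- function(times, events, group, reference = NULL) {
  group <- as.factor(group)
  if (sum(events) == 0) stop_ctx("no events; Cox model undefined")
  if (nlevels(droplevels(group)) < 2) stop_ctx("need >= 2 groups")
  if (!is.null(reference)) group <- stats::relevel(group, ref = reference)
  fit <- tryCatch(
    survival::coxph(survival::Surv(times, as.integer(events)) ~ group,
                    ties = "breslow"),
    warning = function(w) {
      f <- suppressWarnings(
        survival::coxph(survival::Surv(times, as.integer(events)) ~ group,
                        ties = "breslow"))
      attr(f, "fit_warning") <- conditionMessage(w)
      f
    })
  co <- summary(fit)
  se <- co$coefficients[, "se(coef)"]
  converged <- is.null(attr(fit, "fit_warning")) &&
    all(is.finite(stats::coef(fit))) && all(se < 50)
  if (!converged && any(!is.finite(stats::coef(fit))))
    stop_ctx("Cox fit degenerate (non-finite coefficients)")
  res <- data.frame(
    group = sub("^group", "", rownames(co$coefficients)),
    hr = co$coefficients[, "exp(coef)"],
    lower = co$conf.int[, "lower .95"],
    upper = co$conf.int[, "upper .95"],
    p_value = co$coefficients[, "Pr(>|z|)"],
    row.names = NULL)
  attr(res, "converged") <- converged
  attr(res, "reference") <- levels(group)[1]
  class(res) <- c("cox_result", "data.frame")
  res
}

# Rank-statistic AUC: concordant pairs plus half ties, over all
# between-class pairs (equivalent to the Mann-Whitney U statistic).
auc_rank <- function(values, labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop_ctx("both classes must be present")
  r <- rank(values)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC-based dichotomization cutoff (Youden index)
#'
#' AUC by the rank statistic (ties counted half); the cutoff maximizes
#' Youden's J = sensitivity + specificity - 1 over candidate thresholds at
#' midpoints between adjacent sorted unique values, with ties in J broken
#' towards higher sensitivity (lower cutoff).
#'
#' @param values continuous marker (higher = more positive-like).
#' @param labels binary outcome (both classes required).
#' @return list of class `cutoff_result`: `cutoff`, `sensitivity`,
#'   `specificity`, `auc`.
#' @export
roc_cutoff <- function(values, labels) {
  labels <- as.logical(labels)
  if (length(values) != length(labels)) stop_ctx("lengths differ")
  if (all(labels) || !any(labels)) stop_ctx("both classes must be present")
  auc <- auc_rank(values, labels)
  u <- sort(unique(values))
  if (length(u) < 2) stop_ctx("marker is constant")
  cand <- (u[-1] + u[-length(u)]) / 2
  n1 <- sum(labels); n0 <- sum(!labels)
  sens <- vapply(cand, function(t) sum(values > t & labels) / n1, numeric(1))
  spec <- vapply(cand, function(t) sum(values <= t & !labels) / n0, numeric(1))
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)
  best <- best[which.max(sens[best])]   # ties towards higher sensitivity
  structure(list(cutoff = cand[best], sensitivity = sens[best],
                 specificity = spec[best], auc = auc),
            class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf("<cutoff %.4g: sens %.3f, spec %.3f, AUC %.3f>\n",
              x$cutoff, x$sensitivity, x$specificity, x$auc))
  invisible(x)
}
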