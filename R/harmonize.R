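#' Fit a ComBat location-scale harmonization model
#'
#' Parametric empirical-Bayes ComBat, applied directly to the numeric values
#' of a radiomic feature table across scanner batches: each feature is
#' standardized against its grand (batch-size-weighted) mean and pooled
#' variance, per-batch location (gamma) and scale (delta^2) parameters are
#' estimated and shrunk across features towards batch-level priors (normal
#' prior on gamma, inverse-gamma on delta^2) by the standard iterative
#' empirical-Bayes solver, and the resulting adjustments can be applied to
#' the fitted table or to new rows from the same batches.
#'
#' @param features data.frame or matrix of numeric features (rows =
#'   patients). Non-numeric columns are rejected; subset first.
#' @param batch batch label per row (>= 2 distinct batches).
#' @param min_batch_size minimum patients per batch (default 3).
#' @param covariates optional numeric design matrix of biological covariates
#'   to protect during standardization (off by default).
#' @param tol,max_iter empirical-Bayes convergence control (absolute change
#'   < `tol`, default 1e-6, at most `max_iter` = 500 iterations).
#' @return object of class `combat_model`.
#' @export
combat_fit <- function(features, batch, min_batch_size = 3,
                       covariates = NULL, tol = 1e-6, max_iter = 500) {
  X <- as.matrix(features)
  if (!is.numeric(X)) stop_ctx("features must be numeric")
  if (any(!is.finite(X))) stop_ctx("features contain missing or non-finite values")
  batch <- as.character(batch)
  if (length(batch) != nrow(X)) stop_ctx("batch length must match rows")
  levels_b <- unique(batch)
  if (length(levels_b) < 2) stop_ctx("ComBat needs at least 2 batches")
  nb <- table(batch)
  small <- names(nb)[nb < min_batch_size]
  if (length(small) > 0)
    stop_ctx("batch(es) below min_batch_size ", min_batch_size, ": ",
             paste(small, collapse = ", "))
  p <- ncol(X); n <- nrow(X)
  feat_names <- colnames(X) %||% paste0("f", seq_len(p))

  # design: batch indicators (+ optional covariates)
  B <- stats::model.matrix(~ 0 + factor(batch, levels = levels_b))
  colnames(B) <- levels_b
  D <- if (is.null(covariates)) B else cbind(B, as.matrix(covariates))
  beta <- solve(crossprod(D), crossprod(D, X))          # least squares
  nbw <- as.numeric(nb[levels_b]) / n
  grand_mean <- as.numeric(nbw %*% beta[seq_along(levels_b), , drop = FALSE])
  fitted_full <- D %*% beta
  resid <- X - fitted_full
  pooled_var <- colMeans(resid^2)
  zero <- pooled_var <= .Machine$double.eps * 100
  if (any(zero))
    stop_ctx("zero-variance feature(s): ", paste(feat_names[zero], collapse = ", "))

  # covariate contribution (kept out of standardization, restored at apply)
  stand_mean <- matrix(grand_mean, n, p, byrow = TRUE)
  if (!is.null(covariates)) {
    cov_part <- as.matrix(covariates) %*% beta[-seq_along(levels_b), , drop = FALSE]
    stand_mean <- stand_mean + cov_part
  }
  Z <- (X - stand_mean) / matrix(sqrt(pooled_var), n, p, byrow = TRUE)

  gamma_hat <- do.call(rbind, lapply(levels_b, function(b)
    colMeans(Z[batch == b, , drop = FALSE])))
  delta2_hat <- do.call(rbind, lapply(levels_b, function(b)
    apply(Z[batch == b, , drop = FALSE], 2, stats::var)))
  rownames(gamma_hat) <- rownames(delta2_hat) <- levels_b

  gamma_star <- gamma_hat
  delta2_star <- delta2_hat
  for (bi in seq_along(levels_b)) {
    b <- levels_b[bi]
    zb <- Z[batch == b, , drop = FALSE]
    n_b <- nrow(zb)
    g <- gamma_hat[bi, ]; d2 <- delta2_hat[bi, ]
    gbar <- mean(g); tau2 <- stats::var(g)
    m <- mean(d2); s2 <- stats::var(d2)
    a_prior <- (2 * s2 + m^2) / s2
    b_prior <- (m * s2 + m^3) / s2
    g_new <- g; d2_new <- d2
    for (it in seq_len(max_iter)) {
      g_old <- g_new; d2_old <- d2_new
      g_new <- (n_b * tau2 * g + d2_new * gbar) / (n_b * tau2 + d2_new)
      ss <- colSums((zb - matrix(g_new, n_b, p, byrow = TRUE))^2)
      d2_new <- (b_prior + 0.5 * ss) / (n_b / 2 + a_prior - 1)
      if (max(abs(g_new - g_old), abs(d2_new - d2_old)) < tol) break
    }
    gamma_star[bi, ] <- g_new
    delta2_star[bi, ] <- d2_new
  }
  structure(list(batches = levels_b, features = feat_names,
                 grand_mean = stats::setNames(grand_mean, feat_names),
                 pooled_var = stats::setNames(pooled_var, feat_names),
                 gamma_star = gamma_star, delta_star = sqrt(delta2_star),
                 has_covariates = !is.null(covariates),
                 cov_beta = if (is.null(covariates))
                   NULL else beta[-seq_along(levels_b), , drop = FALSE]),
            class = "combat_model")
}

#' @export
print.combat_model <- function(x, ...) {
  cat(sprintf("<combat_model: %d features, %d batches (%s)>\n",
              length(x$features), length(x$batches),
              paste(x$batches, collapse = ", ")))
  invisible(x)
}

#' Apply a fitted ComBat model to a feature table
#'
#' Standardizes each row against the model's grand location/scale, removes
#' the shrunken batch location/scale for the row's batch, and maps back:
#' `(z - gamma*_b) / delta*_b * sqrt(pooled_var) + grand_mean`. Row order
#' and ids are preserved.
#'
#' @param model a [combat_fit()] model.
#' @param features numeric feature table with the model's columns.
#' @param batch batch label per row; must be known to the model.
#' @param covariates covariate matrix, required iff the model was fit with one.
#' @return harmonized table of the same shape (data.frame in, data.frame out).
#' @export
combat_apply <- function(model, features, batch, covariates = NULL) {
  was_df <- is.data.frame(features)
  X <- as.matrix(features)
  batch <- as.character(batch)
  unknown <- setdiff(unique(batch), model$batches)
  if (length(unknown) > 0)
    stop_ctx("batch label(s) not seen at fit: ", paste(unknown, collapse = ", "))
  if (!identical(colnames(X) %||% model$features, model$features))
    X <- X[, model$features, drop = FALSE]
  if (model$has_covariates && is.null(covariates))
    stop_ctx("model was fit with covariates; supply them")
  n <- nrow(X); p <- ncol(X)
  stand_mean <- matrix(model$grand_mean, n, p, byrow = TRUE)
  if (model$has_covariates)
    stand_mean <- stand_mean + as.matrix(covariates) %*% model$cov_beta
  sdm <- matrix(sqrt(model$pooled_var), n, p, byrow = TRUE)
  Z <- (X - stand_mean) / sdm
  bi <- match(batch, model$batches)
  Zadj <- (Z - model$gamma_star[bi, , drop = FALSE]) /
    model$delta_star[bi, , drop = FALSE]
  out <- Zadj * sdm + stand_mean
  if (was_df) as.data.frame(out) else out
}

#' Serialize / restore a ComBat model as JSON
#' @param model a `combat_model`.
#' @param path file path.
#' @return `path` (write) or the restored model (read).
#' @export
combat_write <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname combat_write
#' @export
combat_read <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("gamma_star", "delta_star")) {
    mat <- as.matrix(m[[f]])                  # row-major JSON -> R matrix
    dimnames(mat) <- list(m$batches, m$features)
    m[[f]] <- mat
  }
  m$grand_mean <- stats::setNames(as.numeric(m$grand_mean), m$features)
  m$pooled_var <- stats::setNames(as.numeric(m$pooled_var), m$features)
  if (is.null(m$has_covariates)) m$has_covariates <- FALSE
  structure(m, class = "combat_model")
}
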