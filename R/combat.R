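# Empirical-Bayes location/scale batch harmonization (parametric ComBat).
#
# Model per feature g and subject j in batch i:
#   y_ijg = alpha_g + X_j beta_g + sigma_g * (gamma_ig + delta_ig e_ijg)
# Standardization pools batches by least squares; batch locations gamma
# are shrunk toward a normal prior, batch scales delta^2 toward an
# inverse-gamma prior, with hyperparameters set by method of moments.
# Fitting and application are separated so a serialized model can be
# re-applied and so covariate structure (age, sex, group) is restored,
# not scrubbed.

# method-of-moments inverse-gamma hyperparameters for delta^2
.aprior <- function(d2) {
  m <- mean(d2); s2 <- stats::var(d2)
  (2 * s2 + m^2) / s2
}
.bprior <- function(d2) {
  m <- mean(d2); s2 <- stats::var(d2)
  (m * s2 + m^3) / s2
}

# EB iterative solution for one batch (vectorized over features).
.eb_solve <- function(Z_batch, g_hat, d_hat, g_bar, t2, a, b,
                      conv = 1e-4, max_iter = 500) {
  n <- nrow(Z_batch)
  g_new <- g_hat; d_new <- d_hat
  sum2 <- function(g) colSums(sweep(Z_batch, 2, g)^2)
  for (it in seq_len(max_iter)) {
    g_old <- g_new; d_old <- d_new
    g_new <- (n * t2 * g_hat + d_new * g_bar) / (n * t2 + d_new)
    d_new <- (b + 0.5 * sum2(g_new)) / (n / 2 + a - 1)
    change <- max(abs(g_new - g_old) / pmax(abs(g_old), 1e-12),
                  abs(d_new - d_old) / pmax(abs(d_old), 1e-12))
    if (change < conv) break
  }
  list(gamma_star = g_new, delta_star = d_new)
}

#' Fit an empirical-Bayes batch-harmonization model
#'
#' @param features Numeric matrix or data frame, subjects x features.
#' @param batch Batch label per subject (at least 2 subjects per batch).
#' @param covariates Optional numeric matrix/data frame of biological
#'   covariates to preserve (e.g. age, sex indicator, group indicator);
#'   coerced to a numeric model matrix without intercept.
#' @param eb Use empirical-Bayes shrinkage (default `TRUE`; turned off
#'   automatically when there are fewer than 2 features).
#' @return Object of class `combat_model`: batch levels and sizes, grand
#'   mean `alpha_hat`, covariate coefficients `beta_hat`, pooled feature
#'   SD `sigma_hat`, and per-batch shrunk location `gamma_star` /
#'   variance ratio `delta_star` (all per feature). Zero-variance features
#'   are flagged and passed through unharmonized (with a warning).
#' @seealso [combat_apply()], [harmonization_report()]
#' @export
combat_fit <- function(features, batch, covariates = NULL, eb = TRUE) {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  feat_names <- colnames(x) %||% sprintf("f%d", seq_len(ncol(x)))
  colnames(x) <- feat_names
  batch <- as.character(batch)
  if (length(batch) != nrow(x))
    stopf("batch labels (%d) do not match subjects (%d)", length(batch), nrow(x))
  levels <- sort(unique(batch))
  n_i <- vapply(levels, function(b) sum(batch == b), integer(1))
  if (any(n_i < 2))
    stopf("batch '%s' has fewer than 2 subjects", levels[which(n_i < 2)[1]])
  if (any(!is.finite(x))) stopf("features must be finite")
  n <- nrow(x); p <- ncol(x)
  zero_var <- apply(x, 2, stats::sd) == 0
  if (any(zero_var))
    warning(sprintf("%d zero-variance feature(s) passed through unharmonized: %s",
                    sum(zero_var),
                    paste(utils::head(feat_names[zero_var], 5), collapse = ", ")))
  B <- 1 * outer(batch, levels, "==")
  colnames(B) <- levels
  C <- NULL
  if (!is.null(covariates)) {
    C <- stats::model.matrix(~ ., data = as.data.frame(covariates))[, -1, drop = FALSE]
    if (nrow(C) != n) stopf("covariates do not match subjects")
  }
  X <- cbind(B, C)
  if (qr(X)$rank < ncol(X))
    stopf("design (batch + covariates) is rank-deficient; a covariate is confounded with batch")
  # least-squares standardization fit pooling batches
  beta_full <- solve(crossprod(X), crossprod(X, x))
  gamma_hat_ls <- beta_full[seq_along(levels), , drop = FALSE]
  alpha_hat <- as.numeric((n_i / n) %*% gamma_hat_ls)
  beta_cov <- if (is.null(C)) matrix(0, 0, p) else
    beta_full[-seq_along(levels), , drop = FALSE]
  stand_mean <- matrix(alpha_hat, n, p, byrow = TRUE)
  if (!is.null(C)) stand_mean <- stand_mean + C %*% beta_cov
  # pooled SD of residuals about the batch + covariate fit
  resid_full <- x - X %*% beta_full
  sigma_hat <- sqrt(colSums(resid_full^2) / n)
  sigma_use <- ifelse(zero_var | sigma_hat == 0, 1, sigma_hat)
  Z <- (x - stand_mean) / matrix(sigma_use, n, p, byrow = TRUE)
  gamma_star <- delta_star <- matrix(NA_real_, length(levels), p,
                                     dimnames = list(levels, feat_names))
  use_eb <- eb && p >= 2
  for (bi in seq_along(levels)) {
    sel <- batch == levels[bi]
    Zb <- Z[sel, , drop = FALSE]
    g_hat <- colMeans(Zb)
    d_hat <- apply(Zb, 2, stats::var)
    d_hat[!is.finite(d_hat) | d_hat <= 0] <- 1
    if (use_eb) {
      g_bar <- mean(g_hat); t2 <- stats::var(g_hat)
      a <- .aprior(d_hat); b <- .bprior(d_hat)
      if (!is.finite(t2) || t2 <= 0 || !is.finite(a) || !is.finite(b)) {
        gamma_star[bi, ] <- g_hat; delta_star[bi, ] <- d_hat
      } else {
        sol <- .eb_solve(Zb, g_hat, d_hat, g_bar, t2, a, b)
        gamma_star[bi, ] <- sol$gamma_star
        delta_star[bi, ] <- sol$delta_star
      }
    } else {
      gamma_star[bi, ] <- g_hat; delta_star[bi, ] <- d_hat
    }
  }
  gamma_star[, zero_var] <- 0
  delta_star[, zero_var] <- 1
  structure(list(
    batch_levels = levels, n_per_batch = n_i,
    feature_names = feat_names, zero_variance = zero_var,
    alpha_hat = stats::setNames(alpha_hat, feat_names),
    beta_hat = beta_cov,
    covariate_names = if (is.null(C)) character(0) else colnames(C),
    sigma_hat = stats::setNames(sigma_use, feat_names),
    gamma_star = gamma_star, delta_star = delta_star,
    eb = use_eb
  ), class = "combat_model")
}

#' @export
print.combat_model <- function(x, ...) {
  cat(sprintf("combat_model: %d features, batches %s (n = %s), %s\n",
              length(x$feature_names),
              paste(x$batch_levels, collapse = "/"),
              paste(x$n_per_batch, collapse = "/"),
              if (x$eb) "EB shrinkage" else "no shrinkage"))
  invisible(x)
}

#' Apply a fitted harmonization model
#'
#' Standardizes with the stored grand mean, covariate coefficients and
#' pooled SD, removes the shrunk batch location and scale, then restores
#' the covariate and grand-mean structure.
#'
#' @param features Subjects x features table (same features as the fit).
#' @param batch Batch label per subject; must be levels seen at fit time.
#' @param model A `combat_model`.
#' @param covariates Covariates as supplied to [combat_fit()] (same
#'   columns), or `NULL` if none were used.
#' @return Harmonized table, same shape and type as `features`.
#' @export
combat_apply <- function(features, batch, model, covariates = NULL) {
  df <- is.data.frame(features)
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  batch <- as.character(batch)
  if (!all(batch %in% model$batch_levels))
    stopf("unseen batch label(s): %s",
          paste(setdiff(unique(batch), model$batch_levels), collapse = ", "))
  if (!identical(colnames(x), model$feature_names)) {
    if (is.null(colnames(x)) && ncol(x) == length(model$feature_names))
      colnames(x) <- model$feature_names
    else stopf("features do not match the fitted model")
  }
  n <- nrow(x); p <- ncol(x)
  C <- NULL
  if (length(model$covariate_names)) {
    if (is.null(covariates)) stopf("model was fitted with covariates; supply them")
    C <- stats::model.matrix(~ ., data = as.data.frame(covariates))[, -1, drop = FALSE]
    if (!identical(colnames(C), model$covariate_names))
      stopf("covariates do not match the fitted model")
  }
  stand_mean <- matrix(model$alpha_hat, n, p, byrow = TRUE)
  if (!is.null(C)) stand_mean <- stand_mean + C %*% model$beta_hat
  Z <- (x - stand_mean) / matrix(model$sigma_hat, n, p, byrow = TRUE)
  bi <- match(batch, model$batch_levels)
  Zadj <- (Z - model$gamma_star[bi, , drop = FALSE]) /
    sqrt(model$delta_star[bi, , drop = FALSE])
  out <- Zadj * matrix(model$sigma_hat, n, p, byrow = TRUE) + stand_mean
  out[, model$zero_variance] <- x[, model$zero_variance]
  if (df) {
    res <- as.data.frame(out)
    rownames(res) <- rownames(features)
    res
  } else out
}

#' Between-batch variance fractions before and after harmonization
#'
#' For each feature, the fraction of total sum of squares explained by
#' batch (an eta-squared), computed on the pre- and post-harmonization
#' tables; features whose post fraction still exceeds a threshold are
#' flagged.
#'
#' @param pre,post Matched subjects x features tables.
#' @param batch Batch label per subject.
#' @param flag_threshold Post-harmonization fraction above which a feature
#'   is flagged as still batch-associated (default 0.05).
#' @return Object of class `harmonization_report`: data frame with
#'   `feature`, `pre_fraction`, `post_fraction`, `flagged`.
#' @export
harmonization_report <- function(pre, post, batch, flag_threshold = 0.05) {
  pre <- as.matrix(pre); post <- as.matrix(post)
  if (!all(dim(pre) == dim(post))) stopf("pre/post tables have different shapes")
  frac <- function(x) {
    gm <- colMeans(x)
    tot <- colSums(sweep(x, 2, gm)^2)
    bss <- 0
    for (b in unique(batch)) {
      sel <- batch == b
      bss <- bss + sum(sel) * (colMeans(x[sel, , drop = FALSE]) - gm)^2
    }
    ifelse(tot > 0, bss / tot, 0)
  }
  res <- data.frame(
    feature = colnames(pre) %||% sprintf("f%d", seq_len(ncol(pre))),
    pre_fraction = frac(pre), post_fraction = frac(post),
    row.names = NULL, stringsAsFactors = FALSE)
  res$flagged <- res$post_fraction > flag_threshold
  structure(res, class = c("harmonization_report", "data.frame"))
}

#' Harmonize a set of connectivity matrices
#'
#' Vectorizes the upper triangle (7381 edges for 122 regions) as features,
#' fits and applies the harmonization model, and re-symmetrizes. Entries
#' pushed outside (-1, 1) are reported (count attribute), never clipped.
#'
#' @param matrices Named list of symmetric matrices with identical
#'   dimnames.
#' @param batch Batch label per matrix.
#' @param covariates Optional covariates to preserve (see [combat_fit()]).
#' @return List: `matrices` (harmonized), `model` (`combat_model`),
#'   `n_out_of_range` (entries outside (-1, 1) after harmonization).
#' @export
harmonize_matrices <- function(matrices, batch, covariates = NULL) {
  labs <- rownames(matrices[[1]])
  ut <- upper.tri(matrices[[1]])
  edges <- t(vapply(matrices, function(m) m[ut], numeric(sum(ut))))
  model <- combat_fit(edges, batch, covariates)
  adj <- combat_apply(edges, batch, model, covariates)
  n_out <- sum(abs(adj) >= 1)
  out <- lapply(seq_along(matrices), function(s) {
    m <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
    m[ut] <- adj[s, ]
    m <- m + t(m)
    diag(m) <- 1
    m
  })
  names(out) <- names(matrices)
  list(matrices = out, model = model, n_out_of_range = n_out)
}
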