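# Statistical battery: planned t-tests with Bonferroni-corrected p and
# Cohen d, mixed repeated-measures ANOVA via the multivariate approach on
# within-subject contrasts (Wilks' lambda with Rao's F, and Pillai's
# trace), partial eta squared, Pearson correlations, and edgewise group
# t-maps.

#' Bonferroni correction
#'
#' `min(1, m * p)` for an explicit family size `m` (which may differ from
#' the length of the p-vector when tests are planned across tables).
#'
#' @param p Uncorrected p-value(s) in \[0, 1\].
#' @param m Family size (>= 1).
#' @return Corrected p-value(s).
#' @export
bonferroni <- function(p, m) {
  if (any(m < 1)) stopf("family size m must be >= 1")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p must lie in [0, 1]")
  pmin(1, m * p)
}

#' Partial eta squared from an F statistic
#'
#' `F * df1 / (F * df1 + df2)` -- the conversion that reproduces reported
#' effect sizes from printed F values and degrees of freedom.
#'
#' @param f F statistic (>= 0).
#' @param df1,df2 Numerator and denominator degrees of freedom (>= 1).
#' @return Partial eta squared in \[0, 1).
#' @export
#' @examples
#' partial_eta_from_F(6.30, 1, 204) # ~0.03
partial_eta_from_F <- function(f, df1, df2) {
  if (any(df1 < 1) || any(df2 < 1)) stopf("degrees of freedom must be >= 1")
  if (any(f < 0)) stopf("F must be >= 0")
  f * df1 / (f * df1 + df2)
}

.ttest_result <- function(mean, sd, n, mean_diff = NA_real_, t, df, p, m, d) {
  structure(data.frame(mean = mean, sd = sd, n = n, mean_diff = mean_diff,
                       t = t, df = df, p_uncorrected = p,
                       p_bonferroni = bonferroni(p, m), cohen_d = d,
                       row.names = NULL),
            class = c("ttest_result", "data.frame"))
}

#' One-sample t-test (raw values or summary statistics)
#'
#' Tests a mean against `mu` (default 0, the control reference for
#' Z-scored measures). Accepts either a raw sample or the summary triplet
#' `(mean, sd, n)` -- both give identical results for matching summaries.
#' Cohen d is reported as a magnitude, `|mean - mu| / sd`; the sign is
#' carried by the mean.
#'
#' @param x Numeric sample (or `NULL` when summaries are given).
#' @param mean,sd,n Summary statistics (used when `x` is `NULL`).
#' @param mu Null value (default 0).
#' @param m Bonferroni family size (default 1 = no correction).
#' @return One-row data frame: mean, sd, n, t, df, uncorrected and
#'   corrected p, Cohen d.
#' @export
#' @examples
#' one_sample_t(mean = -0.56, sd = 1.01, n = 136) # t ~ -6.47
one_sample_t <- function(x = NULL, mean = NULL, sd = NULL, n = NULL,
                         mu = 0, m = 1) {
  if (!is.null(x)) {
    if (length(x) < 2) stopf("need n >= 2")
    mean <- base::mean(x); sd <- stats::sd(x); n <- length(x)
  }
  if (is.null(mean) || is.null(sd) || is.null(n))
    stopf("supply either `x` or all of mean, sd, n")
  if (n < 2) stopf("need n >= 2")
  if (sd <= 0) {
    # degenerate sample exactly at the null value: t = 0, p = 1
    if (isTRUE(all.equal(mean, mu)))
      return(.ttest_result(mean, sd, n, NA_real_, 0, n - 1, 1, m, 0))
    stopf("sd must be > 0")
  }
  t <- (mean - mu) / (sd / sqrt(n))
  df <- n - 1
  p <- 2 * stats::pt(-abs(t), df)
  .ttest_result(mean, sd, n, NA_real_, t, df, p, m, abs(mean - mu) / sd)
}

#' Paired t-test
#'
#' One-sample t on the element-wise differences `a - b` (e.g. ipsilateral
#' minus contralateral within patients); `mean_diff` is `mean(a - b)` and
#' Cohen d is `|mean_diff| / sd(a - b)`.
#'
#' @param a,b Matched numeric vectors.
#' @param m Bonferroni family size.
#' @return One-row data frame as in [one_sample_t()] with `mean_diff`.
#' @export
paired_t <- function(a, b, m = 1) {
  if (length(a) != length(b)) stopf("paired samples differ in length")
  if (length(a) < 2) stopf("need n >= 2 pairs")
  d <- a - b
  sdd <- stats::sd(d)
  if (sdd == 0) {
    t <- 0; p <- 1; cd <- 0
  } else {
    t <- base::mean(d) / (sdd / sqrt(length(d)))
    p <- 2 * stats::pt(-abs(t), length(d) - 1)
    cd <- abs(base::mean(d)) / sdd
  }
  .ttest_result(base::mean(a), stats::sd(a), length(a), base::mean(d),
                t, length(d) - 1, p, m, cd)
}

#' Independent two-sample t-test
#'
#' Pooled-variance (equal-variance) form by default,
#' `df = n_a + n_b - 2`; Welch's unequal-variance form behind
#' `var_equal = FALSE`. Cohen d uses the pooled SD.
#'
#' @param a,b Numeric samples (each n >= 2).
#' @param var_equal Pooled-variance t (default `TRUE`).
#' @param m Bonferroni family size.
#' @return One-row data frame; `mean_diff` is `mean(a) - mean(b)`.
#' @export
independent_t <- function(a, b, var_equal = TRUE, m = 1) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stopf("each group needs n >= 2")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) stopf("degenerate: zero variance in both groups")
  md <- base::mean(a) - base::mean(b)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  if (var_equal) {
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- se^4 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  t <- md / se
  p <- 2 * stats::pt(-abs(t), df)
  .ttest_result(base::mean(a), stats::sd(a), na, md, t, df, p, m,
                abs(md) / sqrt(sp2))
}

#' Pearson correlation with Bonferroni-corrected p
#'
#' @param x,y Numeric vectors (n >= 3, finite, non-degenerate).
#' @param m Bonferroni family size.
#' @return One-row data frame: `r`, `n`, `t`, `p_uncorrected`,
#'   `p_corrected`.
#' @export
pearson_corr <- function(x, y, m = 1) {
  if (length(x) != length(y)) stopf("x and y differ in length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stopf("need n >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stopf("zero variance")
  r <- stats::cor(x, y)
  t <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(t), n - 2)
  data.frame(r = r, n = n, t = t, p_uncorrected = p,
             p_corrected = bonferroni(p, m), row.names = NULL)
}

# Orthonormal contrast matrix (k x (k-1)) spanning differences between k
# levels; rows of t(C) are orthogonal to the unit vector.
orth_contrasts <- function(k) {
  C <- stats::contr.helmert(k)
  sweep(C, 2, sqrt(colSums(C^2)), "/")
}

# Multivariate test of L %*% Beta = 0 in the mlm Z = X Beta + E.
# Returns Wilks and Pillai rows with their F approximations.
.mlm_test <- function(Z, X, L) {
  n <- nrow(Z); p <- ncol(Z)
  qrX <- qr(X)
  Bhat <- qr.coef(qrX, Z)
  E <- crossprod(Z - X %*% Bhat)
  XtXi <- chol2inv(chol(crossprod(X)))
  LB <- L %*% Bhat
  H <- t(LB) %*% solve(L %*% XtXi %*% t(L)) %*% LB
  q <- nrow(L)                       # hypothesis df
  v <- n - qrX$rank                  # error df
  s <- min(p, q)
  # Wilks' lambda, Rao's F approximation
  lambda <- det(E) / det(E + H)
  tt <- if (p^2 + q^2 - 5 > 0) sqrt((p^2 * q^2 - 4) / (p^2 + q^2 - 5)) else 1
  w <- v - (p - q + 1) / 2
  df1_w <- p * q
  df2_w <- w * tt - (p * q - 2) / 2
  F_w <- if (lambda > 0) (1 - lambda^(1 / tt)) / lambda^(1 / tt) * df2_w / df1_w else Inf
  # Pillai's trace
  V <- sum(diag(H %*% solve(H + E)))
  mm <- (abs(p - q) - 1) / 2
  nn <- (v - p - 1) / 2
  df1_p <- s * (2 * mm + s + 1)
  df2_p <- s * (2 * nn + s + 1)
  F_p <- if (V < s) (2 * nn + s + 1) / (2 * mm + s + 1) * V / (s - V) else Inf
  data.frame(
    statistic = c("wilks", "pillai"),
    value = c(lambda, V),
    F = c(F_w, F_p),
    df1 = c(df1_w, df1_p),
    df2 = c(df2_w, df2_p),
    p = c(stats::pf(F_w, df1_w, df2_w, lower.tail = FALSE),
          stats::pf(F_p, df1_p, df2_p, lower.tail = FALSE)),
    row.names = NULL)
}

#' Mixed repeated-measures ANOVA (multivariate approach)
#'
#' One between-subjects factor and one or two within-subject factors on a
#' complete crossed design. Within-subject effects and their interactions
#' with group are tested multivariately on orthonormal difference
#' contrasts -- Wilks' lambda with Rao's F approximation and Pillai's
#' trace are both reported (they coincide when the hypothesis has one
#' degree of freedom). The between-subjects effect is the univariate
#' ANOVA of the subject means across within-conditions. The between
#' design uses sum-to-zero coding, so the within main effects are tests
#' of the unweighted grand mean.
#'
#' @param data Long data frame.
#' @param dv,subject,between Column names for the value, subject id, and
#'   between-subjects factor.
#' @param within Character vector of one or two within-subject factor
#'   column names.
#' @return Data frame of class `mixed_anova`: one row per (effect,
#'   statistic) with `F`, `df1`, `df2`, `p`, `partial_eta_sq`
#'   (`F*df1/(F*df1+df2)`).
#' @export
mixed_anova <- function(data, dv, subject, between, within) {
  if (!all(c(dv, subject, between, within) %in% names(data)))
    stopf("missing column(s) in `data`")
  wfac <- lapply(within, function(w) factor(data[[w]]))
  cond <- interaction(wfac, sep = ":", lex.order = TRUE, drop = FALSE)
  ks <- vapply(wfac, nlevels, integer(1))
  subj <- as.character(data[[subject]])
  usubj <- unique(subj)
  ncond <- prod(ks)
  tab <- table(subj)
  if (any(tab != ncond)) {
    bad <- names(tab)[tab != ncond][1]
    stopf("incomplete within design for subject %s (%d of %d conditions)",
          bad, tab[bad], ncond)
  }
  # wide response matrix, conditions ordered with the first within factor
  # varying slowest (matches the kronecker construction below)
  lev <- levels(cond)
  Y <- matrix(NA_real_, length(usubj), ncond,
              dimnames = list(usubj, lev))
  Y[cbind(match(subj, usubj), match(as.character(cond), lev))] <- data[[dv]]
  grp <- factor(data[[between]][match(usubj, subj)])
  mixed_anova_wide(Y, grp, ks, within_names = within)
}

#' @rdname mixed_anova
#' @param Y Wide response matrix (subjects x within-conditions), columns
#'   ordered with the first within factor varying slowest.
#' @param group Between-subjects factor (one entry per row of `Y`).
#' @param k Integer vector of within-factor level counts (length 1 or 2).
#' @param within_names Labels used for the within factors in the output.
#' @export
mixed_anova_wide <- function(Y, group, k, within_names = NULL) {
  group <- factor(group)
  g <- nlevels(group)
  if (any(table(group) < 2)) stopf("every between group needs >= 2 subjects")
  if (ncol(Y) != prod(k)) stopf("ncol(Y) != prod(k)")
  if (is.null(within_names))
    within_names <- paste0("W", seq_along(k))
  n <- nrow(Y)
  X <- cbind(1, stats::contr.sum(g)[as.integer(group), , drop = FALSE])
  effects <- list()
  if (length(k) == 1) {
    effects[[within_names[1]]] <- orth_contrasts(k[1])
  } else {
    C1 <- orth_contrasts(k[1]); C2 <- orth_contrasts(k[2])
    j1 <- matrix(1 / k[1], k[1], 1); j2 <- matrix(1 / k[2], k[2], 1)
    effects[[within_names[1]]] <- kronecker(C1, j2)
    effects[[within_names[2]]] <- kronecker(j1, C2)
    effects[[paste(within_names, collapse = ":")]] <- kronecker(C1, C2)
  }
  L_within <- matrix(0, 1, g); L_within[1, 1] <- 1           # grand mean
  L_group <- cbind(0, diag(g - 1))                           # group rows
  rows <- list()
  for (nm in names(effects)) {
    M <- effects[[nm]]
    Z <- Y %*% M
    r1 <- .mlm_test(Z, X, L_within)
    r1$effect <- nm
    r2 <- .mlm_test(Z, X, L_group)
    r2$effect <- paste(nm, "group", sep = ":")
    rows[[length(rows) + 1L]] <- r1
    rows[[length(rows) + 1L]] <- r2
  }
  # between-subjects effect: univariate ANOVA on subject means
  ybar <- rowMeans(Y)
  fit <- stats::lm(ybar ~ group)
  an <- stats::anova(fit)
  rows[[length(rows) + 1L]] <- data.frame(
    statistic = "univariate", value = NA_real_,
    F = an$`F value`[1], df1 = an$Df[1], df2 = an$Df[2],
    p = an$`Pr(>F)`[1], effect = "group", row.names = NULL)
  out <- do.call(rbind, rows)
  out$partial_eta_sq <- partial_eta_from_F(out$F, out$df1, out$df2)
  out <- out[, c("effect", "statistic", "value", "F", "df1", "df2", "p",
                 "partial_eta_sq")]
  class(out) <- c("mixed_anova", "data.frame")
  out
}

#' Edgewise group t-map for one thalamic subdivision
#'
#' Independent t-tests (pooled variance) comparing two sets of subjects
#' on every edge from the given subdivision node to each other region;
#' p-values are left uncorrected (exploratory map).
#'
#' @param mats_a,mats_b Lists of label-aligned connectivity matrices.
#' @param subdivision,side Thalamic node selector.
#' @param atlas Atlas data frame.
#' @return Data frame of class `edge_stat_map`: `target`, `t`,
#'   `p_uncorrected` (one row per other region, 121 for the full atlas).
#' @export
edgewise_map <- function(mats_a, mats_b, subdivision, side,
                         atlas = thalamus_atlas()) {
  if (!length(mats_a) || !length(mats_b)) stopf("both matrix sets must be non-empty")
  if (!identical(rownames(mats_a[[1]]), rownames(mats_b[[1]])))
    stopf("matrix sets have mismatched region labels")
  node <- thalamic_region(subdivision, side, atlas)
  targets <- setdiff(rownames(mats_a[[1]]), node)
  ea <- vapply(mats_a, function(m) m[node, targets], numeric(length(targets)))
  eb <- vapply(mats_b, function(m) m[node, targets], numeric(length(targets)))
  res <- lapply(seq_along(targets), function(i) {
    r <- independent_t(ea[i, ], eb[i, ])
    data.frame(target = targets[i], t = r$t, p_uncorrected = r$p_uncorrected,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  class(out) <- c("edge_stat_map", "data.frame")
  out
}

#' Mean control connectivity profile of a thalamic subdivision
#'
#' Age/sex-adjusted (via the control GLM), hemisphere-averaged mean edge
#' values from the subdivision to every other bilateral region pair
#' (midline regions averaged across the two thalamic nodes), ranked
#' descending; thalamo-thalamic edges are excluded by default.
#'
#' @param mats Named list of control connectivity matrices.
#' @param subdivision Thalamic subdivision.
#' @param subjects Optional metadata (`subject_id`, `age`, `sex`) for
#'   covariate adjustment; `NULL` skips adjustment.
#' @param top_k Number of strongest connections to return (`Inf` = all).
#' @param include_thalamic Keep other thalamic subdivisions as targets.
#' @param atlas Atlas data frame.
#' @return Data frame `target` (base region name), `value`, ranked
#'   descending, at most `top_k` rows.
#' @export
control_profile <- function(mats, subdivision, subjects = NULL, top_k = 10,
                            include_thalamic = FALSE,
                            atlas = thalamus_atlas()) {
  if (length(mats) < 2) stopf("need >= 2 control matrices")
  nl <- thalamic_region(subdivision, "L", atlas)
  nr <- thalamic_region(subdivision, "R", atlas)
  keep <- atlas[atlas$region != nl & atlas$region != nr, ]
  if (!include_thalamic) keep <- keep[keep$class != "thalamic_subdivision", ]
  bases <- unique(keep$base)
  per_subj <- vapply(mats, function(m) {
    vapply(bases, function(b) {
      rows <- keep[keep$base == b, ]
      if (nrow(rows) == 2) {
        tl <- rows$region[rows$hemisphere == "L"]
        tr <- rows$region[rows$hemisphere == "R"]
        (m[nl, tl] + m[nr, tr]) / 2          # hemisphere-matched average
      } else {
        (m[nl, rows$region] + m[nr, rows$region]) / 2
      }
    }, numeric(1))
  }, numeric(length(bases)))
  vals <- if (is.null(subjects)) rowMeans(per_subj) else {
    i <- match(names(mats), subjects$subject_id)
    if (anyNA(i)) stopf("matrix names must match subject ids for adjustment")
    X <- cbind(1, subjects$age[i], as.numeric(subjects$sex[i] == "M"))
    Xbar <- colMeans(X)
    apply(per_subj, 1, function(y) {
      b <- qr.coef(qr(X), y)
      sum(Xbar * b) + mean(y - X %*% b)     # value at the mean covariates
    })
  }
  out <- data.frame(target = bases, value = vals, stringsAsFactors = FALSE)
  out <- out[order(-out$value), ]
  rownames(out) <- NULL
  utils::head(out, top_k)
}
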