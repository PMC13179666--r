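# Normative scoring: eTIV adjustment (volumes), control-referenced GLM for
# age and sex, per-hemisphere Z-scores, and ipsi/contra relabeling.
#
# The normative model is fitted on controls only (W-score convention): a
# model fitted on the pooled sample would absorb disease effects into the
# reference. Z-scoring is strictly hemisphere-matched -- a right-sided
# feature is scored against right-sided control values -- and only then
# are patient values relabeled ipsilateral/contralateral to the focus.

# Stage bookkeeping: measure tables carry a `stage` attribute so the
# pipeline can refuse out-of-order application.
measure_stage <- function(x) attr(x, "measure_stage")

set_stage <- function(x, stage) {
  attr(x, "measure_stage") <- stage
  x
}

.check_stage <- function(x, allowed, op) {
  st <- measure_stage(x)
  if (!is.null(st) && !st %in% allowed)
    stopf("%s expects a table at stage %s, got '%s' (enforced order: raw -> harmonized -> etiv_adjusted -> z)",
          op, paste(sQuote(allowed), collapse = " or "), st)
  invisible(x)
}

#' Adjust volumes for estimated total intracranial volume
#'
#' Residual method: each volume feature is regressed on eTIV in controls;
#' the eTIV-predicted component is subtracted from every subject and the
#' control mean restored. A ratio variant (`volume / eTIV`, rescaled to
#' the control mean eTIV) is available behind `method`.
#'
#' @param volumes Data frame `subject_id` + volume feature columns.
#' @param subjects Subject metadata with `subject_id`, `group`, `etiv`.
#' @param method `"residual"` (default) or `"ratio"`.
#' @return Adjusted volume table (stage `etiv_adjusted`).
#' @export
adjust_for_etiv <- function(volumes, subjects, method = c("residual", "ratio")) {
  method <- match.arg(method)
  .check_stage(volumes, c("raw", "harmonized"), "adjust_for_etiv")
  i <- match(volumes$subject_id, subjects$subject_id)
  if (anyNA(i)) stopf("volume table contains unknown subjects")
  etiv <- subjects$etiv[i]
  if (anyNA(etiv) || any(etiv <= 0)) stopf("missing or non-positive eTIV")
  ctrl <- subjects$group[i] == "control"
  if (sum(ctrl) < 3) stopf("need at least 3 controls for eTIV adjustment")
  feats <- setdiff(names(volumes), "subject_id")
  out <- volumes
  if (method == "residual") {
    e0 <- mean(etiv[ctrl])
    v_etiv <- stats::var(etiv[ctrl])
    for (f in feats) {
      # zero eTIV spread: nothing to regress out, adjustment is the identity
      b <- if (v_etiv > 0) stats::cov(volumes[[f]][ctrl], etiv[ctrl]) / v_etiv else 0
      out[[f]] <- volumes[[f]] - b * (etiv - e0)
    }
  } else {
    e0 <- mean(etiv[ctrl])
    for (f in feats) out[[f]] <- volumes[[f]] / etiv * e0
  }
  set_stage(out, "etiv_adjusted")
}

#' Fit the control-referenced normative model
#'
#' Per feature, an ordinary least-squares fit of `value ~ age + sex` on
#' controls, with the control residual SD stored per hemisphere-specific
#' feature as the Z denominator.
#'
#' @param values Data frame `subject_id` + feature columns (controls and
#'   patients may be mixed; only controls are used).
#' @param subjects Metadata with `subject_id`, `group`, `age`, `sex`.
#' @param min_controls Minimum number of controls (default 10).
#' @return Object of class `normative_model`: coefficient matrix
#'   (intercept, age, sexM) and residual SD per feature.
#' @export
fit_normative_model <- function(values, subjects, min_controls = 10) {
  i <- match(values$subject_id, subjects$subject_id)
  if (anyNA(i)) stopf("value table contains unknown subjects")
  ctrl <- which(subjects$group[i] == "control")
  if (length(ctrl) < min_controls)
    stopf("need >= %d controls, got %d", min_controls, length(ctrl))
  age <- subjects$age[i][ctrl]
  sex <- subjects$sex[i][ctrl]
  if (length(unique(sex)) < 2)
    stopf("controls include a single sex; the age+sex design is singular")
  X <- cbind(intercept = 1, age = age, sexM = as.numeric(sex == "M"))
  feats <- setdiff(names(values), "subject_id")
  Y <- as.matrix(values[ctrl, feats, drop = FALSE])
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stopf("singular normative design")
  coefs <- qr.coef(qrX, Y)
  resid <- Y - X %*% coefs
  rsd <- apply(resid, 2, stats::sd)
  if (any(rsd <= 0)) stopf("zero control residual SD for feature %s",
                           feats[which(rsd <= 0)[1]])
  structure(list(features = feats, coefficients = coefs,
                 residual_sd = stats::setNames(rsd, feats),
                 n_controls = length(ctrl)),
            class = "normative_model")
}

#' @export
print.normative_model <- function(x, ...) {
  cat(sprintf("normative_model: %d features, fitted on %d controls (value ~ age + sex)\n",
              length(x$features), x$n_controls))
  invisible(x)
}

#' Z-score values against the control normative model
#'
#' `Z = (value - predicted(age, sex)) / control residual SD`, computed
#' within each hemisphere-specific feature. Applied to the fitting
#' controls this yields mean 0, SD 1 per feature by construction.
#'
#' @param values Data frame `subject_id` + feature columns.
#' @param subjects Metadata with `subject_id`, `age`, `sex`.
#' @param model A [fit_normative_model()] result covering the features.
#' @return Z table (stage `z`), same shape as `values`.
#' @export
zscore_to_controls <- function(values, subjects, model) {
  feats <- setdiff(names(values), "subject_id")
  missing <- setdiff(feats, model$features)
  if (length(missing))
    stopf("feature(s) absent from the normative model: %s",
          paste(missing, collapse = ", "))
  i <- match(values$subject_id, subjects$subject_id)
  X <- cbind(1, subjects$age[i], as.numeric(subjects$sex[i] == "M"))
  out <- values
  for (f in feats) {
    pred <- as.numeric(X %*% model$coefficients[, f])
    out[[f]] <- (values[[f]] - pred) / model$residual_sd[f]
  }
  set_stage(out, "z")
}

#' Relabel hemispheric features as ipsi/contralateral to the seizure focus
#'
#' Patients with a left focus keep left values as ipsilateral; a right
#' focus mirrors the mapping. Controls have no focus and are excluded
#' (they retain left/right labels in the input table). The operation is
#' idempotent: a table already keyed ipsi/contra is returned unchanged.
#'
#' @param ztable Data frame `subject_id` + `<subdivision>_<L|R>` columns.
#' @param subjects Metadata with `subject_id`, `group`, `focus_side`.
#' @return Data frame of patients only, columns
#'   `<subdivision>_<ipsi|contra>`.
#' @export
relabel_laterality <- function(ztable, subjects) {
  feats <- setdiff(names(ztable), "subject_id")
  if (all(grepl("_(ipsi|contra)$", feats))) return(ztable)
  if (!all(grepl("_(L|R)$", feats)))
    stopf("features must be suffixed _L/_R (or already _ipsi/_contra)")
  base <- unique(sub("_(L|R)$", "", feats))
  i <- match(ztable$subject_id, subjects$subject_id)
  pat <- which(subjects$group[i] != "control")
  side <- subjects$focus_side[i][pat]
  if (any(!side %in% c("L", "R")))
    stopf("patient %s has no focus side",
          ztable$subject_id[pat[which(!side %in% c("L", "R"))[1]]])
  out <- data.frame(subject_id = ztable$subject_id[pat],
                    stringsAsFactors = FALSE)
  for (b in base) {
    l <- ztable[[paste0(b, "_L")]][pat]
    r <- ztable[[paste0(b, "_R")]][pat]
    out[[paste0(b, "_ipsi")]] <- ifelse(side == "L", l, r)
    out[[paste0(b, "_contra")]] <- ifelse(side == "L", r, l)
  }
  set_stage(out, measure_stage(ztable) %||% "z")
}
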