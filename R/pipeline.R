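# End-to-end orchestration: simulate (or load) -> inject scanner effects
# -> harmonize -> graph metrics -> eTIV / covariate adjustment -> Z ->
# ipsi/contra relabeling -> statistical battery -> report tables.

.measures <- c("strength", "volume")

#' Run the full analysis pipeline
#'
#' Stage order is fixed: scanner harmonization first (volumes and
#' connectivity edges), then node-strength AUC from the harmonized
#' matrices, eTIV adjustment for volumes, control-referenced age/sex
#' Z-scoring per hemisphere, ipsi/contra relabeling, and the statistical
#' battery (mixed ANOVAs, planned one-sample and paired t-tests with
#' Bonferroni correction, clinical subgroup ANOVAs, structure-function
#' and duration correlations, edgewise t-maps).
#'
#' @param cohort A `thal_cohort` from [simulate_cohort()] /
#'   [read_cohort()], or `NULL` to simulate from `config`.
#' @param config A [cohort_config()] used when `cohort` is `NULL`.
#' @param out_dir Optional output directory for TSV/JSON artifacts.
#' @param inject_batch Inject the configured scanner batch effect into
#'   the raw features before harmonization (default `TRUE`; the
#'   simulated raw data are scanner-free, so this emulates acquisition
#'   on two scanners).
#' @param strength_weights `"signed"` (default) or `"absolute"` node
#'   strength.
#' @param etiv_method `"residual"` (default) or `"ratio"`.
#' @param m_onesample Bonferroni family for one-sample tests (default 8:
#'   4 subdivisions x 2 lateralities per measure per group).
#' @param m_paired Bonferroni family for paired laterality tests
#'   (default 4: subdivisions).
#' @param edgewise Compute edgewise patient-vs-control t-maps (slower).
#' @return Object of class `thal_result`: staged measure tables, fitted
#'   models, `table2_like` (mixed ANOVAs), `table3_like` (planned
#'   t-tests), `subgroup_anovas`, `correlations`, optional
#'   `edgewise_maps`, and the configuration echo.
#' @export
run_pipeline <- function(cohort = NULL, config = cohort_config(),
                         out_dir = NULL, inject_batch = TRUE,
                         strength_weights = "signed",
                         etiv_method = "residual",
                         m_onesample = 8, m_paired = 4,
                         edgewise = FALSE) {
  if (is.null(cohort)) cohort <- simulate_cohort(config)
  subjects <- cohort$subjects
  validate_subjects(subjects)
  feats <- volume_feature_names()

  # --- scanner effect injection (simulation only) ----------------------
  volumes_raw <- set_stage(cohort$volumes, "raw")
  mats_raw <- cohort$matrices
  be <- config$batch_effect
  if (inject_batch && !is.null(be) &&
      (be$additive != 0 || be$scale != 1) &&
      length(unique(subjects$scanner_batch)) > 1) {
    vol_sd <- config$vol_noise_frac * config$vol_mean[
      sub("_(L|R)$", "", feats)]
    vm <- inject_batch_effects(as.matrix(volumes_raw[, feats]),
                               subjects$scanner_batch, be$target,
                               additive = be$additive * vol_sd,
                               scale = be$scale)
    volumes_raw[, feats] <- vm
    ut <- upper.tri(mats_raw[[1]])
    edges <- t(vapply(mats_raw, function(m) m[ut], numeric(sum(ut))))
    edges <- inject_batch_effects(edges, subjects$scanner_batch, be$target,
                                  additive = be$additive, scale = be$scale)
    labs <- rownames(mats_raw[[1]])
    mats_raw <- lapply(seq_along(mats_raw), function(s) {
      m <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
      m[ut] <- edges[s, ]
      m <- m + t(m); diag(m) <- 1
      m
    })
    names(mats_raw) <- subjects$subject_id
  }

  # --- harmonization ---------------------------------------------------
  covars <- data.frame(age = subjects$age,
                       sexM = as.numeric(subjects$sex == "M"),
                       patient = as.numeric(subjects$group != "control"))
  multi_batch <- length(unique(subjects$scanner_batch)) > 1
  if (multi_batch) {
    vol_model <- combat_fit(as.matrix(volumes_raw[, feats]),
                            subjects$scanner_batch, covars)
    volumes_h <- volumes_raw
    volumes_h[, feats] <- combat_apply(as.matrix(volumes_raw[, feats]),
                                       subjects$scanner_batch, vol_model, covars)
    hm <- harmonize_matrices(mats_raw, subjects$scanner_batch, covars)
    mats_h <- hm$matrices
    conn_model <- hm$model
  } else {
    vol_model <- conn_model <- NULL
    volumes_h <- volumes_raw
    mats_h <- mats_raw
  }
  volumes_h <- set_stage(volumes_h, "harmonized")

  # --- graph metrics on harmonized matrices ----------------------------
  atlas <- thalamus_atlas()
  th_labels <- atlas$region[atlas$class == "thalamic_subdivision"]
  auc <- t(vapply(mats_h, function(m)
    strength_auc_matrix(m, weights = strength_weights)[th_labels],
    numeric(length(th_labels))))
  # Thal_Anterior_L -> anterior_L etc., matching the volume feature names
  colnames(auc) <- paste(atlas$subdivision[match(th_labels, atlas$region)],
                         atlas$hemisphere[match(th_labels, atlas$region)],
                         sep = "_")
  auc_tab <- data.frame(subject_id = names(mats_h),
                        as.data.frame(auc[, feats]), row.names = NULL)
  auc_tab <- set_stage(auc_tab, "harmonized")

  # --- normalization ---------------------------------------------------
  volumes_adj <- adjust_for_etiv(volumes_h, subjects, method = etiv_method)
  norm_models <- list(
    volume = fit_normative_model(volumes_adj, subjects),
    strength = fit_normative_model(auc_tab, subjects))
  z_lr <- list(
    volume = zscore_to_controls(volumes_adj, subjects, norm_models$volume),
    strength = zscore_to_controls(auc_tab, subjects, norm_models$strength))
  z_ic <- lapply(z_lr, relabel_laterality, subjects = subjects)

  # --- statistical battery ---------------------------------------------
  table2 <- run_group_anovas(z_lr, z_ic, subjects)
  table3 <- run_planned_tests(z_ic, subjects, m_onesample, m_paired)
  subgroups <- lapply(c(HS_vs_NoHS = "HS_vs_NoHS", FBTCS = "FBTCS",
                        status_epilepticus = "status_epilepticus",
                        etiology = "etiology", seizure_free = "seizure_free"),
                      function(g) try_subgroup(z_ic, subjects, g))
  correlations <- run_correlations(z_ic, subjects)
  edge_maps <- if (edgewise) run_edgewise(mats_h, subjects) else NULL

  result <- structure(list(
    subjects = subjects,
    volumes_raw = volumes_raw, volumes_harmonized = volumes_h,
    volumes_adjusted = volumes_adj,
    auc = auc_tab, z_lr = z_lr, z_ic = z_ic,
    harmonization_models = list(volume = vol_model, connectivity = conn_model),
    normative_models = norm_models,
    table2_like = table2, table3_like = table3,
    subgroup_anovas = subgroups, correlations = correlations,
    edgewise_maps = edge_maps,
    config = config,
    switches = list(strength_weights = strength_weights,
                    etiv_method = etiv_method,
                    m_onesample = m_onesample, m_paired = m_paired,
                    inject_batch = inject_batch)
  ), class = "thal_result")
  if (!is.null(out_dir)) write_result(result, cohort, out_dir)
  result
}

#' @export
print.thal_result <- function(x, ...) {
  cat(sprintf("thal_result: %d subjects; %d mixed-ANOVA rows, %d planned-test rows\n",
              nrow(x$subjects), nrow(x$table2_like), nrow(x$table3_like)))
  invisible(x)
}

# Mixed ANOVAs: (A) control vs all-epilepsy with the 8 hemispheric
# nucleus features as one within factor; (B) TLE/FLE/PQE with nuclei x
# laterality within (patients only, ipsi/contra frame).
run_group_anovas <- function(z_lr, z_ic, subjects) {
  out <- list()
  feats <- volume_feature_names()
  for (ms in .measures) {
    zl <- z_lr[[ms]]
    grp2 <- ifelse(subjects$group[match(zl$subject_id, subjects$subject_id)] ==
                     "control", "control", "epilepsy")
    a <- mixed_anova_wide(as.matrix(zl[, feats]), grp2, k = 8L,
                          within_names = "nuclei")
    a$measure <- ms; a$model <- "overall_vs_controls"
    out[[length(out) + 1L]] <- a
    zi <- z_ic[[ms]]
    grp3 <- subjects$group[match(zi$subject_id, subjects$subject_id)]
    cols <- as.vector(t(outer(.subdivisions, c("ipsi", "contra"),
                              paste, sep = "_")))
    b <- mixed_anova_wide(as.matrix(zi[, cols]), droplevels(factor(grp3)),
                          k = c(4L, 2L),
                          within_names = c("nuclei", "laterality"))
    b$measure <- ms; b$model <- "TLE_FLE_PQE"
    out[[length(out) + 1L]] <- b
  }
  do.call(rbind, out)
}

# Planned one-sample tests against the control mean (zero) and paired
# ipsi-vs-contra tests, per group x measure x subdivision.
run_planned_tests <- function(z_ic, subjects, m_onesample = 8, m_paired = 4) {
  rows <- list()
  for (ms in .measures) {
    zi <- z_ic[[ms]]
    grp <- as.character(subjects$group[match(zi$subject_id,
                                             subjects$subject_id)])
    for (g in c("all", "TLE", "FLE", "PQE")) {
      sel <- if (g == "all") rep(TRUE, nrow(zi)) else grp == g
      if (sum(sel) < 2) next
      for (sd_ in .subdivisions) {
        for (lat in c("ipsi", "contra")) {
          r <- one_sample_t(zi[[paste(sd_, lat, sep = "_")]][sel],
                            m = m_onesample)
          rows[[length(rows) + 1L]] <- data.frame(
            group = g, measure = ms, nucleus = sd_, side = lat, r,
            stringsAsFactors = FALSE)
        }
        rp <- paired_t(zi[[paste(sd_, "ipsi", sep = "_")]][sel],
                       zi[[paste(sd_, "contra", sep = "_")]][sel],
                       m = m_paired)
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, measure = ms, nucleus = sd_, side = "paired", rp,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Clinical subgroup three-way mixed ANOVA
#'
#' Runs the subgroup x nuclei x laterality mixed ANOVA on the ipsi/contra
#' Z tables, for a clinical dichotomy; subjects with unknown labels for
#' that variable are excluded per analysis (not globally), so analyzed N
#' varies by grouping.
#'
#' @param z_ic Named list of ipsi/contra Z tables (`volume`, `strength`),
#'   as produced by [run_pipeline()] (`$z_ic`).
#' @param subjects Subject metadata table.
#' @param grouping One of `"HS_vs_NoHS"` (within TLE), `"FBTCS"`,
#'   `"status_epilepticus"`, `"etiology"` (acquired vs congenital),
#'   `"seizure_free"`.
#' @return A `mixed_anova` data frame with `measure`, `model`,
#'   `n_analyzed` columns appended.
#' @export
subgroup_contrast <- function(z_ic, subjects,
                              grouping = c("HS_vs_NoHS", "FBTCS",
                                           "status_epilepticus", "etiology",
                                           "seizure_free")) {
  grouping <- match.arg(grouping)
  sel_fun <- switch(grouping,
    HS_vs_NoHS = function(s) ifelse(s$group == "TLE" &
                                      s$hs_status %in% c("HS", "NoHS"),
                                    s$hs_status, NA),
    FBTCS = function(s) ifelse(s$group != "control" &
                                 s$fbtcs %in% c("yes", "no"), s$fbtcs, NA),
    status_epilepticus = function(s)
      ifelse(s$group != "control" & s$status_epilepticus %in% c("yes", "no"),
             s$status_epilepticus, NA),
    etiology = function(s) ifelse(s$group != "control" &
                                    s$etiology %in% c("acquired", "congenital"),
                                  s$etiology, NA),
    seizure_free = function(s) ifelse(s$group != "control" &
                                        s$seizure_free %in% c("yes", "no"),
                                      s$seizure_free, NA))
  lab <- sel_fun(subjects)
  cols <- as.vector(t(outer(.subdivisions, c("ipsi", "contra"),
                            paste, sep = "_")))
  out <- list()
  for (ms in .measures) {
    zi <- z_ic[[ms]]
    gl <- lab[match(zi$subject_id, subjects$subject_id)]
    keep <- !is.na(gl)
    if (length(unique(gl[keep])) < 2)
      stopf("subgroup '%s' has an empty level after exclusions", grouping)
    a <- mixed_anova_wide(as.matrix(zi[keep, cols]), factor(gl[keep]),
                          k = c(4L, 2L),
                          within_names = c("nuclei", "laterality"))
    a$measure <- ms; a$model <- grouping
    a$n_analyzed <- sum(keep)
    out[[length(out) + 1L]] <- a
  }
  do.call(rbind, out)
}

try_subgroup <- function(z_ic, subjects, grouping) {
  tryCatch(subgroup_contrast(z_ic, subjects, grouping),
           error = function(e) NULL)
}

# Structure-function and duration correlations across patients, per
# (subdivision, laterality); Bonferroni family = pairs tested per block.
run_correlations <- function(z_ic, subjects) {
  zi_v <- z_ic$volume; zi_s <- z_ic$strength
  i <- match(zi_v$subject_id, subjects$subject_id)
  dur <- subjects$duration_years[i]
  rows <- list()
  pairs <- expand.grid(nucleus = .subdivisions, side = c("ipsi", "contra"),
                       stringsAsFactors = FALSE)
  m <- nrow(pairs)
  for (k in seq_len(m)) {
    f <- paste(pairs$nucleus[k], pairs$side[k], sep = "_")
    r1 <- pearson_corr(zi_v[[f]], zi_s[[f]], m = m)
    rows[[length(rows) + 1L]] <- data.frame(
      analysis = "volume_vs_strength", nucleus = pairs$nucleus[k],
      side = pairs$side[k], r1, stringsAsFactors = FALSE)
    if (sum(is.finite(dur)) >= 3) {
      r2 <- pearson_corr(dur, zi_v[[f]], m = m)
      r3 <- pearson_corr(dur, zi_s[[f]], m = m)
      rows[[length(rows) + 1L]] <- data.frame(
        analysis = "duration_vs_volume", nucleus = pairs$nucleus[k],
        side = pairs$side[k], r2, stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        analysis = "duration_vs_strength", nucleus = pairs$nucleus[k],
        side = pairs$side[k], r3, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Edgewise maps: patients expressed in a focus-left frame (right-focus
# matrices mirrored), controls averaged with their mirror image; the "L"
# node of the aligned frame is ipsilateral.
run_edgewise <- function(mats, subjects, sides = "ipsi") {
  atlas <- thalamus_atlas()
  i <- match(names(mats), subjects$subject_id)
  is_ctrl <- subjects$group[i] == "control"
  ctrl <- lapply(mats[is_ctrl],
                 function(m) (m + mirror_matrix(m, atlas)) / 2)
  pats <- mats[!is_ctrl]
  focus <- subjects$focus_side[i][!is_ctrl]
  pats <- lapply(seq_along(pats), function(k)
    if (focus[k] == "R") mirror_matrix(pats[[k]], atlas) else pats[[k]])
  out <- list()
  for (sd_ in .subdivisions) {
    for (side in sides) {
      phys <- if (side == "ipsi") "L" else "R"
      mp <- edgewise_map(pats, ctrl, sd_, phys, atlas)
      mp$subdivision <- sd_; mp$side <- side
      out[[length(out) + 1L]] <- mp
    }
  }
  do.call(rbind, out)
}

#' Validate pipeline inputs
#'
#' Reports (never throws): matrix asymmetry (max |M - t(M)|), region
#' labels disagreeing with the atlas, non-positive volumes or eTIV,
#' missing metadata (focus side for patients, age, sex, batch).
#'
#' @param cohort A `thal_cohort`-like list with `subjects`, `volumes`,
#'   `matrices`.
#' @param atlas Atlas data frame.
#' @return Data frame `subject`, `check`, `detail`; zero rows when clean.
#' @export
validate_inputs <- function(cohort, atlas = thalamus_atlas()) {
  probs <- list()
  add <- function(subject, check, detail)
    probs[[length(probs) + 1L]] <<- data.frame(
      subject = subject, check = check, detail = detail,
      stringsAsFactors = FALSE)
  s <- cohort$subjects
  for (k in seq_len(nrow(s))) {
    if (s$group[k] != "control" && !s$focus_side[k] %in% c("L", "R"))
      add(s$subject_id[k], "focus_side", "patient without focus side")
    if (is.na(s$age[k]) || s$age[k] <= 0)
      add(s$subject_id[k], "age", "missing or non-positive age")
    if (!s$sex[k] %in% c("F", "M"))
      add(s$subject_id[k], "sex", "missing sex")
    if (is.na(s$scanner_batch[k]) || s$scanner_batch[k] == "")
      add(s$subject_id[k], "scanner_batch", "missing batch")
    if (is.na(s$etiv[k]) || s$etiv[k] <= 0)
      add(s$subject_id[k], "etiv", "missing or non-positive eTIV")
  }
  if (!is.null(cohort$volumes)) {
    feats <- setdiff(names(cohort$volumes), "subject_id")
    bad <- which(as.matrix(cohort$volumes[, feats]) <= 0, arr.ind = TRUE)
    if (nrow(bad))
      for (k in seq_len(nrow(bad)))
        add(cohort$volumes$subject_id[bad[k, 1]], "volume",
            sprintf("non-positive %s", feats[bad[k, 2]]))
  }
  for (id in names(cohort$matrices)) {
    m <- cohort$matrices[[id]]
    asym <- max(abs(m - t(m)))
    if (asym > 1e-8)
      add(id, "matrix_symmetry", sprintf("max |M - t(M)| = %.3g", asym))
    if (!identical(sort(rownames(m)), sort(atlas$region)))
      add(id, "matrix_labels", "region labels disagree with the atlas")
  }
  if (length(probs)) do.call(rbind, probs)
  else data.frame(subject = character(0), check = character(0),
                  detail = character(0), stringsAsFactors = FALSE)
}

validate_subjects <- function(subjects) {
  need <- c("subject_id", "group", "age", "sex", "focus_side",
            "scanner_batch", "etiv")
  miss <- setdiff(need, names(subjects))
  if (length(miss)) stopf("subject table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  pat <- subjects$group != "control"
  if (any(pat & !subjects$focus_side %in% c("L", "R")))
    stopf("patient without focus side: %s",
          subjects$subject_id[which(pat &
                                      !subjects$focus_side %in% c("L", "R"))[1]])
  invisible(subjects)
}

# Write pipeline artifacts: staged tables, report TSVs, models, manifest.
write_result <- function(result, cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) if (!is.null(df)) write_tsv(df, file.path(out_dir, name))
  w(result$subjects, "subjects.tsv")
  w(stage_col(result$volumes_raw, "raw"), "volumes_raw.tsv")
  w(stage_col(result$volumes_harmonized, "harmonized"), "volumes_harmonized.tsv")
  w(stage_col(result$volumes_adjusted, "etiv_adjusted"), "volumes_adjusted.tsv")
  w(stage_col(result$auc, "harmonized"), "strength_auc.tsv")
  w(stage_col(result$z_lr$volume, "z"), "volume_z_lr.tsv")
  w(stage_col(result$z_lr$strength, "z"), "strength_z_lr.tsv")
  w(stage_col(result$z_ic$volume, "z"), "volume_z_ipsicontra.tsv")
  w(stage_col(result$z_ic$strength, "z"), "strength_z_ipsicontra.tsv")
  w(result$table2_like, "table2_like.tsv")
  w(result$table3_like, "table3_like.tsv")
  sg <- result$subgroup_anovas[!vapply(result$subgroup_anovas, is.null,
                                       logical(1))]
  if (length(sg)) w(do.call(rbind, sg), "subgroup_anovas.tsv")
  w(result$correlations, "correlations.tsv")
  w(result$edgewise_maps, "edgewise_maps.tsv")
  for (nm in names(result$normative_models))
    write_model_json(result$normative_models[[nm]],
                     file.path(out_dir, sprintf("normative_%s.json", nm)))
  if (!is.null(result$harmonization_models$volume))
    write_model_json(result$harmonization_models$volume,
                     file.path(out_dir, "combat_volumes.json"))
  if (!is.null(cohort$ground_truth)) {
    gt <- cohort$ground_truth
    gt$mean_matrix <- NULL
    jsonlite::write_json(gt, file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("thalnet")),
    seed = result$config$seed,
    switches = result$switches,
    n_subjects = nrow(result$subjects),
    n_per_group = as.list(table(result$subjects$group)),
    stage_rows = list(
      volumes = nrow(result$volumes_raw),
      strength_auc = nrow(result$auc),
      table2_like = nrow(result$table2_like),
      table3_like = nrow(result$table3_like)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

stage_col <- function(df, stage) {
  if (is.null(df)) return(NULL)
  cbind(df, stage = stage)
}
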