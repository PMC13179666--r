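# Synthetic cohort generator.
#
# Emulates the statistical structure of a pediatric focal-epilepsy study:
# a demographics table (group sizes, ages, sex, seizure-focus side,
# scanner batches, clinical labels), THOMAS-style thalamic subdivision
# volumes proportional to intracranial volume, and CONN-style 122x122
# Pearson connectivity matrices generated in Fisher-z space. Group effects
# are planted as standardized shifts (Cohen d units of the control
# residual SD) on specific (measure, subdivision, laterality) targets,
# mapped through each patient's focus side; scanner effects are injected
# separately so harmonization has something real to remove.

.groups <- c("control", "TLE", "FLE", "PQE")
.subdivisions <- c("anterior", "lateral", "medial", "pulvinar")

#' Default planted group effects
#'
#' Per-group mean Z-deviations of patients from the control reference,
#' for node-strength AUC and volume, by subdivision and laterality
#' relative to the seizure focus — the effect pattern the study reports
#' (pulvinar hypoconnectivity across groups, ipsilateral anterior/lateral
#' volume loss, contralateral medial enlargement). The anterior-strength
#' rows are split by hippocampal-sclerosis status within TLE (elevated
#' with HS, reduced without), which plants the nuclei-by-pathology
#' interaction.
#'
#' @return Data frame with columns `measure`, `subdivision`,
#'   `laterality`, `group`, `d`.
#' @export
default_planted_effects <- function() {
  rows <- list(
    # measure, subdivision, laterality, group, d
    c("strength", "anterior", "both",   "TLE_HS",    0.45),
    c("strength", "anterior", "both",   "TLE_NoHS", -0.40),
    c("strength", "lateral",  "ipsi",   "TLE", -0.25),
    c("strength", "lateral",  "contra", "TLE", -0.18),
    c("strength", "medial",   "ipsi",   "TLE", -0.16),
    c("strength", "medial",   "contra", "TLE", -0.29),
    c("strength", "pulvinar", "ipsi",   "TLE", -0.57),
    c("strength", "pulvinar", "contra", "TLE", -0.32),
    c("strength", "anterior", "ipsi",   "FLE", -0.15),
    c("strength", "anterior", "contra", "FLE", -0.23),
    c("strength", "lateral",  "ipsi",   "FLE", -0.23),
    c("strength", "medial",   "contra", "FLE", -0.43),
    c("strength", "pulvinar", "ipsi",   "FLE", -0.57),
    c("strength", "pulvinar", "contra", "FLE", -0.15),
    c("strength", "anterior", "contra", "PQE", -0.19),
    c("strength", "lateral",  "ipsi",   "PQE", -0.14),
    c("strength", "medial",   "contra", "PQE",  0.30),
    c("strength", "pulvinar", "ipsi",   "PQE", -0.51),
    c("strength", "pulvinar", "contra", "PQE", -0.34),
    c("volume", "anterior", "ipsi",   "TLE", -0.64),
    c("volume", "anterior", "contra", "TLE",  0.17),
    c("volume", "lateral",  "ipsi",   "TLE", -0.57),
    c("volume", "lateral",  "contra", "TLE", -0.12),
    c("volume", "medial",   "ipsi",   "TLE",  0.26),
    c("volume", "medial",   "contra", "TLE",  0.45),
    c("volume", "pulvinar", "ipsi",   "TLE", -0.13),
    c("volume", "pulvinar", "contra", "TLE",  0.20),
    c("volume", "anterior", "ipsi",   "FLE", -0.60),
    c("volume", "anterior", "contra", "FLE", -0.32),
    c("volume", "lateral",  "ipsi",   "FLE", -0.51),
    c("volume", "lateral",  "contra", "FLE", -0.16),
    c("volume", "medial",   "ipsi",   "FLE",  0.23),
    c("volume", "medial",   "contra", "FLE",  0.40),
    c("volume", "pulvinar", "ipsi",   "FLE",  0.36),
    c("volume", "pulvinar", "contra", "FLE",  0.26),
    c("volume", "anterior", "ipsi",   "PQE", -0.43),
    c("volume", "lateral",  "ipsi",   "PQE", -0.34),
    c("volume", "medial",   "ipsi",   "PQE",  0.64),
    c("volume", "medial",   "contra", "PQE",  0.95),
    c("volume", "pulvinar", "ipsi",   "PQE", -0.75),
    c("volume", "pulvinar", "contra", "PQE",  0.39)
  )
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- c("measure", "subdivision", "laterality", "group", "d")
  out$d <- as.numeric(out$d)
  out
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults reproduce the study conditions: group sizes 81 TLE / 36 FLE /
#' 19 PQE / 70 controls, pediatric ages (group means 13.1/11.8/13.2/13.4
#' years, SD about 3, truncated to 4-18), roughly 3:1 left-sided foci, all
#' controls plus most patients on the 1.5T scanner batch with later
#' patients on 3T, clinical label frequencies matching the cohort table,
#' and planted effects echoing the reported per-group Z-deviations
#' (see [default_planted_effects()]).
#'
#' @param group_sizes Named counts for control, TLE, FLE, PQE.
#' @param planted_effects Data frame with columns `measure`
#'   (`"strength"`/`"volume"`), `subdivision`, `laterality`
#'   (`"ipsi"`/`"contra"`/`"both"`), `group` (`"all"`, a patient group, or
#'   `"TLE_HS"`/`"TLE_NoHS"`), `d` (standardized shift, |d| <= `d_max`).
#' @param focus_left_fraction Probability that a patient's focus is left.
#' @param batch_3T_frac Per-group probability of the 3T batch.
#' @param batch_additive,batch_scale Scanner-batch location/scale effect
#'   injected by the pipeline (additive in units of the feature residual
#'   SD for volumes, correlation units for edges; scale multiplies
#'   deviations around the feature mean).
#' @param conn_noise_sd Subject-level Fisher-z noise SD for connectivity.
#' @param vol_noise_frac Volume residual SD as a fraction of the
#'   subdivision mean.
#' @param conn_calibration_n Monte-Carlo draws used internally to map a
#'   planted strength-AUC effect size onto a per-edge z shift.
#' @param seed Integer seed; identical configurations (including seed)
#'   regenerate bit-identical cohorts.
#' @param d_max Largest allowed |d| for a planted effect.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(group_sizes = c(control = 70, TLE = 81, FLE = 36, PQE = 19),
                          planted_effects = default_planted_effects(),
                          focus_left_fraction = 0.75,
                          batch_3T_frac = c(control = 0, TLE = 33 / 136,
                                            FLE = 33 / 136, PQE = 33 / 136),
                          batch_additive = 0.1,
                          batch_scale = 1.5,
                          conn_noise_sd = 0.12,
                          vol_noise_frac = 0.06,
                          conn_calibration_n = 80,
                          seed = 1L,
                          d_max = 2) {
  cfg <- list(
    group_sizes = group_sizes,
    age_mean = c(control = 13.4, TLE = 13.1, FLE = 11.8, PQE = 13.2),
    age_sd = c(control = 3.1, TLE = 3.0, FLE = 3.2, PQE = 3.1),
    age_range = c(4, 18),
    sex_female_frac = c(control = 34 / 70, TLE = 46 / 81, FLE = 19 / 36,
                        PQE = 11 / 19),
    focus_left_fraction = focus_left_fraction,
    batch_3T_frac = batch_3T_frac,
    hs_frac = 28 / 81,
    fbtcs_frac = list(TLE = c(29, 46, 6) / 81, FLE = c(8, 27, 1) / 36,
                      PQE = c(8, 11, 0) / 19),
    se_frac = list(TLE = c(21, 60, 0) / 81, FLE = c(8, 27, 1) / 36,
                   PQE = c(4, 15, 0) / 19),
    etiology_frac = list(TLE = c(63, 11, 7) / 81, FLE = c(12, 15, 9) / 36,
                         PQE = c(14, 3, 2) / 19),
    szfree_frac = list(TLE = c(40, 13, 28) / 81, FLE = c(14, 11, 11) / 36,
                       PQE = c(4, 4, 11) / 19),
    duration_mean = c(TLE = 6.5, FLE = 5.8, PQE = 7.6),
    duration_sd = c(TLE = 4.1, FLE = 3.8, PQE = 4.0),
    etiv_mean = 1.45e6, etiv_sd = 1.2e5,
    vol_mean = c(anterior = 140, lateral = 1700, medial = 950,
                 pulvinar = 1450),
    vol_asym_frac = 0.01,        # left minus right, fraction of the mean
    vol_age_slope_frac = 0.005,  # per year, fraction of the mean
    vol_sex_male_frac = 0.03,
    vol_noise_frac = vol_noise_frac,
    conn_noise_sd = conn_noise_sd,
    conn_calibration_n = conn_calibration_n,
    batch_effect = list(additive = batch_additive, scale = batch_scale,
                        target = "batch_3T"),
    planted_effects = planted_effects,
    d_max = d_max,
    seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  gs <- cfg$group_sizes
  if (!all(.groups %in% names(gs)))
    stopf("group_sizes must name %s", paste(.groups, collapse = ", "))
  if (any(gs < 0) || any(gs != round(gs)))
    stopf("group sizes must be non-negative integers")
  fr <- c(cfg$focus_left_fraction, cfg$batch_3T_frac, cfg$hs_frac,
          cfg$sex_female_frac)
  if (any(fr < 0 | fr > 1)) stopf("fractions must lie in [0, 1]")
  pe <- cfg$planted_effects
  if (nrow(pe) > 0) {
    ok_groups <- c("all", "TLE", "FLE", "PQE", "TLE_HS", "TLE_NoHS")
    if (!all(pe$group %in% ok_groups))
      stopf("planted effect group must be one of %s",
            paste(ok_groups, collapse = ", "))
    if (!all(pe$measure %in% c("strength", "volume")))
      stopf("planted effect measure must be 'strength' or 'volume'")
    if (!all(pe$subdivision %in% .subdivisions))
      stopf("unknown subdivision in planted effects")
    if (!all(pe$laterality %in% c("ipsi", "contra", "both")))
      stopf("planted effect laterality must be ipsi, contra or both")
    if (any(abs(pe$d) > cfg$d_max))
      stopf("|d| of a planted effect exceeds d_max = %g", cfg$d_max)
  }
  if (cfg$batch_effect$scale <= 0) stopf("batch scale must be > 0")
  invisible(cfg)
}

# Truncated-normal draws via inverse CDF (deterministic under the seed).
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  p <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(p, mean, sd)
}

#' Generate the subject metadata table
#'
#' @param config A [cohort_config()].
#' @return Data frame, one row per subject: `subject_id`, `group`, `age`,
#'   `sex`, `focus_side` (`none` for controls), `scanner_batch`,
#'   `hs_status`, `fbtcs`, `status_epilepticus`, `etiology`,
#'   `seizure_free`, `duration_years` (`NA` for controls), `etiv` (mm^3).
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  with_seed(derive_seed(config$seed, 1L), {
    gs <- config$group_sizes[.groups]
    n <- sum(gs)
    group <- factor(rep(.groups, gs), levels = .groups)
    draw3 <- function(labels, frac, n) {
      if (n == 0) character(0)
      else sample(labels, n, replace = TRUE, prob = frac)
    }
    sub <- data.frame(
      subject_id = sprintf("S%04d", seq_len(n)),
      group = group, stringsAsFactors = FALSE)
    sub$age <- NA_real_; sub$sex <- NA_character_
    sub$focus_side <- "none"
    sub$scanner_batch <- NA_character_
    sub$hs_status <- "NA"; sub$fbtcs <- "unknown"
    sub$status_epilepticus <- "unknown"; sub$etiology <- "NA"
    sub$seizure_free <- "unknown"
    sub$duration_years <- NA_real_
    for (g in .groups) {
      sel <- which(sub$group == g)
      ng <- length(sel)
      if (ng == 0) next
      sub$age[sel] <- rtrunc_norm(ng, config$age_mean[g], config$age_sd[g],
                                  config$age_range[1], config$age_range[2])
      sub$sex[sel] <- draw3(c("F", "M"),
                            c(config$sex_female_frac[g],
                              1 - config$sex_female_frac[g]), ng)
      sub$scanner_batch[sel] <- draw3(
        c("batch_3T", "batch_1p5T"),
        c(config$batch_3T_frac[g], 1 - config$batch_3T_frac[g]), ng)
      if (g == "control") next
      sub$focus_side[sel] <- draw3(c("L", "R"),
                                   c(config$focus_left_fraction,
                                     1 - config$focus_left_fraction), ng)
      sub$fbtcs[sel] <- draw3(c("yes", "no", "unknown"),
                              config$fbtcs_frac[[g]], ng)
      sub$status_epilepticus[sel] <- draw3(c("yes", "no", "unknown"),
                                           config$se_frac[[g]], ng)
      sub$etiology[sel] <- draw3(c("acquired", "congenital", "other"),
                                 config$etiology_frac[[g]], ng)
      sub$seizure_free[sel] <- draw3(c("yes", "no", "unknown"),
                                     config$szfree_frac[[g]], ng)
      dur <- rtrunc_norm(ng, config$duration_mean[g], config$duration_sd[g],
                         0.5, Inf)
      sub$duration_years[sel] <- pmin(dur, sub$age[sel] - 0.5)
      if (g == "TLE")
        sub$hs_status[sel] <- draw3(c("HS", "NoHS"),
                                    c(config$hs_frac, 1 - config$hs_frac), ng)
      else sub$hs_status[sel] <- "NoHS"
    }
    sub$etiv <- rtrunc_norm(n, config$etiv_mean, config$etiv_sd,
                            config$etiv_mean - 4 * config$etiv_sd,
                            config$etiv_mean + 4 * config$etiv_sd)
    sub
  })
}

# Which subjects does a planted-effect row apply to?
.effect_subjects <- function(subjects, group) {
  switch(group,
         all = subjects$group != "control",
         TLE_HS = subjects$group == "TLE" & subjects$hs_status == "HS",
         TLE_NoHS = subjects$group == "TLE" & subjects$hs_status == "NoHS",
         subjects$group == group)
}

# Map effect laterality to the physical side(s) for one subject.
.effect_sides <- function(focus_side, laterality) {
  if (laterality == "both") return(c("L", "R"))
  if (!focus_side %in% c("L", "R"))
    stopf("laterality-specific effect on a subject without a focus side")
  if (laterality == "ipsi") focus_side else setdiff(c("L", "R"), focus_side)
}

volume_feature_names <- function() {
  as.vector(t(outer(.subdivisions, c("L", "R"), paste, sep = "_")))
}

#' Generate THOMAS-style thalamic subdivision volumes
#'
#' Volumes (mm^3) are proportional to each subject's intracranial volume,
#' with a linear age trend, a sex offset, a small leftward asymmetry,
#' Gaussian residual noise, and planted group shifts of `d` times the
#' residual SD applied on the side(s) mapped through the subject's seizure
#' focus.
#'
#' @param subjects Output of [generate_cohort()].
#' @param config The same [cohort_config()].
#' @return Data frame: `subject_id` plus eight columns
#'   `<subdivision>_<L|R>`.
#' @export
generate_volumes <- function(subjects, config = cohort_config()) {
  with_seed(derive_seed(config$seed, 2L), {
    feats <- volume_feature_names()
    n <- nrow(subjects)
    vol <- matrix(NA_real_, n, length(feats),
                  dimnames = list(subjects$subject_id, feats))
    pe <- config$planted_effects
    pe <- pe[pe$measure == "volume", , drop = FALSE]
    for (f in feats) {
      parts <- strsplit(f, "_")[[1]]
      subdiv <- parts[1]; side <- parts[2]
      mu <- config$vol_mean[subdiv]
      asym <- if (side == "L") config$vol_asym_frac / 2 else -config$vol_asym_frac / 2
      base <- mu * (subjects$etiv / config$etiv_mean) *
        (1 + asym + config$vol_age_slope_frac * (subjects$age - 13) +
           config$vol_sex_male_frac * (subjects$sex == "M"))
      shift <- numeric(n)
      if (nrow(pe) > 0) {
        for (r in seq_len(nrow(pe))) {
          if (pe$subdivision[r] != subdiv) next
          who <- which(.effect_subjects(subjects, pe$group[r]))
          for (s in who) {
            sides <- .effect_sides(subjects$focus_side[s], pe$laterality[r])
            if (side %in% sides)
              shift[s] <- shift[s] + pe$d[r] * config$vol_noise_frac * mu
          }
        }
      }
      vol[, f] <- base + shift + stats::rnorm(n, 0, config$vol_noise_frac * mu)
    }
    bad <- which(vol <= 0, arr.ind = TRUE)
    if (nrow(bad) > 0)
      stopf("non-positive volume generated for subject %s, feature %s; reduce the planted effect",
            subjects$subject_id[bad[1, 1]], feats[bad[1, 2]])
    data.frame(subject_id = subjects$subject_id, as.data.frame(vol),
               row.names = NULL, stringsAsFactors = FALSE)
  })
}

# Deterministic population mean connectivity in Fisher-z space.
population_mean_z <- function(atlas = thalamus_atlas()) {
  n <- nrow(atlas)
  hemi <- atlas$hemisphere; lobe <- atlas$lobe; base <- atlas$base
  z <- matrix(0.10, n, n)
  same_hemi <- outer(hemi, hemi, "==") & outer(hemi != "M", hemi != "M", "&")
  z[same_hemi] <- z[same_hemi] + 0.05
  same_lobe <- outer(lobe, lobe, "==")
  z[same_lobe] <- z[same_lobe] + 0.15
  homotopic <- outer(base, base, "==") & !outer(hemi, hemi, "==")
  z[homotopic] <- z[homotopic] + 0.20
  infra <- lobe %in% c("cerebellum", "brainstem")
  cross <- outer(infra, !infra, "&") | outer(!infra, infra, "&")
  z[cross] <- z[cross] - 0.12
  # thalamo-thalamic block
  th <- atlas$class == "thalamic_subdivision"
  z[th, th] <- 0.25
  tt_same_side <- outer(hemi[th], hemi[th], "==")
  z[th, th][tt_same_side] <- 0.35
  tt_homotopic <- outer(atlas$subdivision[th], atlas$subdivision[th], "==") &
    !outer(hemi[th], hemi[th], "==")
  z[th, th][tt_homotopic] <- 0.45
  # subdivision-specific cortical/subcortical profiles
  lobe_boost <- list(
    anterior = c(frontal = 0.15),
    lateral = c(sensorimotor = 0.18, insular = 0.16, temporal = 0.08),
    medial = c(insular = 0.16, sensorimotor = 0.14, temporal = 0.08),
    pulvinar = c(occipital = 0.18, limbic = 0.10, frontal = -0.08))
  spec_boost <- list(
    anterior = c(Amygdala = 0.38, Hippocampus = 0.30,
                 Superior_Temporal_Gyrus_anterior = 0.18,
                 Superior_Temporal_Gyrus_posterior = 0.18,
                 Juxtapositional_Lobule = 0.15, Caudate = 0.15,
                 Putamen = 0.12),
    lateral = c(Lingual_Gyrus = 0.15, Temporal_Fusiform_Cortex_posterior = 0.14,
                Occipital_Fusiform_Gyrus = 0.12,
                Inferior_Frontal_Gyrus_pars_triangularis = 0.15,
                Inferior_Frontal_Gyrus_pars_opercularis = 0.15),
    medial = c(Lingual_Gyrus = 0.14, Temporal_Fusiform_Cortex_posterior = 0.13,
               Amygdala = 0.18, Accumbens = 0.18),
    pulvinar = c(Hippocampus = 0.30, Parahippocampal_Gyrus_anterior = 0.28,
                 Parahippocampal_Gyrus_posterior = 0.26, Amygdala = 0.25,
                 Temporal_Pole = 0.15, Accumbens = 0.18,
                 Insular_Cortex = 0.16, Precuneous_Cortex = 0.22,
                 Cingulate_Gyrus_posterior = 0.22))
  other <- which(!th)
  for (k in which(th)) {
    sd_k <- atlas$subdivision[k]
    lb <- lobe_boost[[sd_k]]; sb <- spec_boost[[sd_k]]
    add <- numeric(length(other))
    hit <- match(lobe[other], names(lb)); ok <- !is.na(hit)
    add[ok] <- add[ok] + lb[hit[ok]]
    hit <- match(base[other], names(sb)); ok <- !is.na(hit)
    add[ok] <- add[ok] + sb[hit[ok]]
    add <- add + 0.03 * (hemi[other] == hemi[k])
    z[k, other] <- z[k, other] + add
    z[other, k] <- z[other, k] + add
  }
  # deterministic low-rank ripple to break magnitude ties
  u <- sin(seq_len(n)); v <- cos(seq_len(n))
  z <- z + 0.02 * outer(u, u) + 0.01 * outer(v, v)
  z <- (z + t(z)) / 2
  diag(z) <- 0
  dimnames(z) <- list(atlas$region, atlas$region)
  z
}

#' Population mean connectivity matrix of the synthetic model
#'
#' The control-population mean is synthetic (no real mean matrix is
#' available): a block structure with hemispheric, homotopic and
#' lobe-community organisation plus subdivision-specific thalamic
#' profiles, defined in Fisher-z space and back-transformed.
#'
#' @param atlas Atlas data frame.
#' @return 122x122 symmetric matrix with unit diagonal.
#' @export
population_mean_matrix <- function(atlas = thalamus_atlas()) {
  r <- tanh(population_mean_z(atlas))
  diag(r) <- 1
  r
}

# Map a planted strength-AUC effect size d to a per-edge Fisher-z shift:
# d * SD(control AUC) / (dAUC / d(delta_z)). Both quantities come from a
# small internal Monte-Carlo at the configured noise level; the
# sensitivity uses paired differences (same noise draw with and without
# the shift), because the density thresholding makes the AUC response to
# an edge shift noticeably steeper under noise than at the mean matrix.
calibrate_strength_shift <- function(mean_z, noise_sd, n_sim, seed,
                                     atlas = thalamus_atlas()) {
  th_idx <- which(atlas$class == "thalamic_subdivision")
  labs <- atlas$region[th_idx]
  n <- nrow(mean_z)
  ut <- upper.tri(mean_z)
  n_ut <- sum(ut)
  delta0 <- -0.02
  n_sens <- max(10L, n_sim %/% 5L)
  auc <- matrix(NA_real_, n_sim, length(th_idx),
                dimnames = list(NULL, labs))
  sens_acc <- matrix(0, n_sens, length(th_idx),
                     dimnames = list(NULL, labs))
  with_seed(seed, {
    for (s in seq_len(n_sim)) {
      zn <- matrix(0, n, n)
      zn[ut] <- stats::rnorm(n_ut, 0, noise_sd)
      zn <- zn + t(zn)
      z1 <- mean_z + zn
      r <- tanh(z1); diag(r) <- 1
      dimnames(r) <- dimnames(mean_z)
      auc[s, ] <- strength_auc_matrix(r)[labs]
      if (s <= n_sens) {
        for (j in seq_along(th_idx)) {
          k <- th_idx[j]
          z2 <- z1
          z2[k, ] <- z2[k, ] + delta0
          z2[, k] <- z2[, k] + delta0
          diag(z2) <- 0
          r2 <- tanh(z2); diag(r2) <- 1
          dimnames(r2) <- dimnames(mean_z)
          sens_acc[s, j] <- (strength_auc_matrix(r2)[labs[j]] - auc[s, j]) /
            delta0
        }
      }
    }
  })
  list(sd_auc = apply(auc, 2, stats::sd),
       sensitivity = colMeans(sens_acc))
}

#' Generate per-subject connectivity matrices
#'
#' Matrices are generated in Fisher-z space (population mean + iid
#' upper-triangle noise + planted shifts on every edge incident to a
#' targeted thalamic node) and back-transformed with `tanh`, so entries
#' stay in (-1, 1) without clipping. Planted node-strength effects are
#' calibrated internally so the targeted node's strength-AUC shifts by
#' `d` control SDs.
#'
#' @inheritParams generate_volumes
#' @return List: `matrices` (named list of 122x122 matrices),
#'   `calibration` (per-node AUC SD, sensitivity, per-effect z shifts).
#' @export
generate_connectivity <- function(subjects, config = cohort_config()) {
  atlas <- thalamus_atlas()
  mean_z <- population_mean_z(atlas)
  pe <- config$planted_effects
  pe <- pe[pe$measure == "strength", , drop = FALSE]
  calib <- NULL
  deltas <- numeric(0)
  if (nrow(pe) > 0) {
    calib <- calibrate_strength_shift(mean_z, config$conn_noise_sd,
                                      config$conn_calibration_n,
                                      derive_seed(config$seed, 4L), atlas)
    # per-effect z shift, computed from the left node (mean matrix is
    # hemispherically near-symmetric)
    deltas <- vapply(seq_len(nrow(pe)), function(r) {
      node <- thalamic_region(pe$subdivision[r], "L", atlas)
      pe$d[r] * calib$sd_auc[node] / calib$sensitivity[node]
    }, numeric(1))
  }
  n <- nrow(mean_z)
  ut <- upper.tri(mean_z)
  node_index <- function(subdiv, side)
    match(thalamic_region(subdiv, side, atlas), atlas$region)
  mats <- with_seed(derive_seed(config$seed, 3L), {
    lapply(seq_len(nrow(subjects)), function(s) {
      z <- mean_z
      if (nrow(pe) > 0) {
        for (r in seq_len(nrow(pe))) {
          if (!.effect_subjects(subjects, pe$group[r])[s]) next
          for (side in .effect_sides(subjects$focus_side[s], pe$laterality[r])) {
            k <- node_index(pe$subdivision[r], side)
            z[k, ] <- z[k, ] + deltas[r]
            z[, k] <- z[, k] + deltas[r]
          }
        }
        diag(z) <- 0
      }
      zn <- matrix(0, n, n)
      zn[ut] <- stats::rnorm(sum(ut), 0, config$conn_noise_sd)
      z <- z + zn + t(zn)
      r_mat <- tanh(z)
      diag(r_mat) <- 1
      dimnames(r_mat) <- dimnames(mean_z)
      r_mat
    })
  })
  names(mats) <- subjects$subject_id
  list(matrices = mats,
       calibration = c(calib, list(effects = cbind(pe, delta_z = deltas))))
}

#' Inject a scanner-batch location/scale effect into a feature table
#'
#' For rows in `target_batch`, each feature y becomes
#' `m + (y - m) * scale + additive`, where `m` is the feature's grand mean
#' of the input table. With `scale = 1` batch means separate by exactly
#' `additive`; with `additive = 0, scale = s` the batch SD is multiplied
#' by `s`.
#'
#' @param features Numeric matrix or data frame (subjects x features).
#' @param batch Character/factor batch label per subject.
#' @param target_batch Batch receiving the effect.
#' @param additive Additive offset (feature units; recycled per feature).
#' @param scale Multiplicative scale (> 0) on deviations from the mean.
#' @return Same shape as `features`, with attribute `batch_offsets`
#'   recording the applied effect.
#' @export
inject_batch_effects <- function(features, batch, target_batch = "batch_3T",
                                 additive = 0, scale = 1) {
  if (!target_batch %in% batch)
    stopf("unknown batch label '%s' (present: %s)", target_batch,
          paste(unique(batch), collapse = ", "))
  if (any(scale <= 0)) stopf("scale must be > 0")
  df <- is.data.frame(features)
  x <- as.matrix(features)
  m <- colMeans(x)
  additive <- rep_len(additive, ncol(x))
  scale <- rep_len(scale, ncol(x))
  sel <- batch == target_batch
  x[sel, ] <- sweep(sweep(sweep(x[sel, , drop = FALSE], 2, m), 2, scale, "*"),
                    2, m + additive, "+")
  out <- if (df) {
    res <- features
    res[] <- as.data.frame(x)
    res
  } else x
  attr(out, "batch_offsets") <- list(target = target_batch,
                                     additive = additive, scale = scale)
  out
}

#' Simulate a full cohort (metadata, volumes, connectivity)
#'
#' @param config A [cohort_config()].
#' @return Object of class `thal_cohort`: `subjects`, `volumes`,
#'   `matrices`, `ground_truth`, `config`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  subjects <- generate_cohort(config)
  volumes <- generate_volumes(subjects, config)
  conn <- generate_connectivity(subjects, config)
  gt <- list(
    group_sizes = as.list(config$group_sizes),
    planted_effects = config$planted_effects,
    strength_calibration = conn$calibration,
    mean_volumes = as.list(config$vol_mean),
    mean_matrix = population_mean_matrix(),
    batch_effect = config$batch_effect,
    seed = config$seed
  )
  structure(list(subjects = subjects, volumes = volumes,
                 matrices = conn$matrices, ground_truth = gt,
                 config = config),
            class = "thal_cohort")
}

#' @export
print.thal_cohort <- function(x, ...) {
  cat(sprintf("thal_cohort: %d subjects (%s), %d matrices, seed %d\n",
              nrow(x$subjects),
              paste(sprintf("%s=%d", names(table(x$subjects$group)),
                            table(x$subjects$group)), collapse = ", "),
              length(x$matrices), x$config$seed))
  invisible(x)
}
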