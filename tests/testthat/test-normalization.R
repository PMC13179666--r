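make_subjects <- function(n_ctrl = 40, n_pat = 30, seed = 21) {
  set.seed(seed)
  n <- n_ctrl + n_pat
  data.frame(
    subject_id = sprintf("S%03d", 1:n),
    group = rep(c("control", "TLE"), c(n_ctrl, n_pat)),
    age = runif(n, 5, 18),
    sex = sample(c("F", "M"), n, replace = TRUE),
    focus_side = rep(c("none", "L"), c(n_ctrl, n_pat)),
    etiv = rnorm(n, 1.45e6, 1.2e5),
    stringsAsFactors = FALSE)
}

test_that("eTIV adjustment removes proportional volume variation", {
  sub <- make_subjects()
  vol <- data.frame(subject_id = sub$subject_id,
                    anterior_L = 1e-4 * sub$etiv,  # exactly proportional
                    anterior_R = 1e-4 * sub$etiv)
  adj <- adjust_for_etiv(vol, sub)
  ctrl <- sub$group == "control"
  expect_lt(sd(adj$anterior_L[ctrl]), 1e-9)
  # identical eTIV -> identity up to a constant
  sub2 <- sub; sub2$etiv <- 1.5e6
  vol2 <- data.frame(subject_id = sub$subject_id,
                     anterior_L = rnorm(nrow(sub), 140, 8))
  adj2 <- adjust_for_etiv(vol2, sub2)
  expect_equal(diff(range(adj2$anterior_L - vol2$anterior_L)), 0,
               tolerance = 1e-9)
})

test_that("a group deficit independent of eTIV survives adjustment", {
  set.seed(8)
  sub <- make_subjects(60, 60)
  pat <- sub$group != "control"
  shift <- -8  # raw-unit deficit unrelated to eTIV
  d_target <- abs(shift) / 8
  vol <- data.frame(subject_id = sub$subject_id,
                    anterior_L = 1e-4 * sub$etiv + rnorm(nrow(sub), 0, 8) +
                      shift * pat)
  d_raw_resid <- abs(mean(vol$anterior_L[pat] - 1e-4 * sub$etiv[pat]) -
                       mean(vol$anterior_L[!pat] - 1e-4 * sub$etiv[!pat])) / 8
  adj <- adjust_for_etiv(vol, sub)
  d_adj <- abs(mean(adj$anterior_L[pat]) - mean(adj$anterior_L[!pat])) /
    sd(adj$anterior_L[!pat] - mean(adj$anterior_L[!pat]))
  expect_equal(d_adj, d_raw_resid, tolerance = 0.02 * d_target + 0.02)
})

test_that("normative GLM recovers planted age slopes; residuals center", {
  set.seed(5)
  sub <- make_subjects(70, 0)
  val <- data.frame(subject_id = sub$subject_id,
                    f_L = 2 + 0.1 * sub$age + 0.3 * (sub$sex == "M") +
                      rnorm(70, 0, 0.3),
                    f_R = rnorm(70))
  mod <- fit_normative_model(val, sub)
  expect_lt(abs(mod$coefficients["age", "f_L"] - 0.1), 0.02)
  expect_lt(abs(mod$coefficients["age", "f_R"]), 0.05)  # null feature
  z <- zscore_to_controls(val, sub, mod)
  expect_lt(abs(mean(z$f_L)), 1e-10)
  expect_equal(sd(z$f_L), 1, tolerance = 1e-10)
  # single-sex controls are a singular design
  sub1 <- sub; sub1$sex <- "F"
  expect_error(fit_normative_model(val, sub1), "single sex")
})

test_that("Z is zero at the control prediction and calibrated on controls", {
  sub <- make_subjects(50, 1)
  set.seed(3)
  val <- data.frame(subject_id = sub$subject_id,
                    f_L = 10 + 0.2 * sub$age + rnorm(51, 0, 0.5))
  mod <- fit_normative_model(val, sub)
  pat <- nrow(sub)
  val$f_L[pat] <- mod$coefficients["intercept", "f_L"] +
    mod$coefficients["age", "f_L"] * sub$age[pat] +
    mod$coefficients["sexM", "f_L"] * (sub$sex[pat] == "M")
  z <- zscore_to_controls(val, sub, mod)
  expect_equal(z$f_L[pat], 0, tolerance = 1e-12)
  expect_error(zscore_to_controls(
    data.frame(subject_id = sub$subject_id, g_L = 1:51), sub, mod),
    "absent from the normative model")
})

test_that("Z calibration is hemisphere-separated", {
  set.seed(13)
  sub <- make_subjects(60, 20)
  val <- data.frame(subject_id = sub$subject_id,
                    f_L = rnorm(80), f_R = rnorm(80))
  ctrl <- sub$group == "control"
  shifted <- val
  shifted$f_R[ctrl] <- shifted$f_R[ctrl] + 5  # right-control shift only
  z0 <- zscore_to_controls(val, sub, fit_normative_model(val, sub))
  z1 <- zscore_to_controls(shifted, sub, fit_normative_model(shifted, sub))
  expect_equal(z1$f_L, z0$f_L, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(z1$f_R[!ctrl], z0$f_R[!ctrl])))
})

test_that("laterality relabeling mirrors by focus side and is idempotent", {
  sub <- data.frame(subject_id = c("C1", "P1", "P2"),
                    group = c("control", "TLE", "TLE"),
                    focus_side = c("none", "L", "R"),
                    stringsAsFactors = FALSE)
  z <- data.frame(subject_id = c("C1", "P1", "P2"),
                  pulvinar_L = c(0.1, -0.7, -0.7),
                  pulvinar_R = c(0.2, 0.3, 0.3))
  ic <- relabel_laterality(z, sub)
  expect_equal(nrow(ic), 2)  # controls excluded
  expect_equal(ic$pulvinar_ipsi, c(-0.7, 0.3))
  expect_equal(ic$pulvinar_contra, c(0.3, -0.7))
  expect_identical(relabel_laterality(ic, sub), ic)
  sub$focus_side[2] <- "none"
  expect_error(relabel_laterality(z, sub), "no focus side")
})

test_that("flipping all focus sides and hemispheres leaves ipsi/contra intact", {
  cfg <- small_config(seed = 77)
  sub <- generate_cohort(cfg)
  vol <- generate_volumes(sub, cfg)
  adj <- adjust_for_etiv(vol, sub)
  z <- zscore_to_controls(adj, sub, fit_normative_model(adj, sub))
  ic <- relabel_laterality(z, sub)
  # mirror world: swap L/R columns and flip every focus side
  zm <- z
  for (s in c("anterior", "lateral", "medial", "pulvinar")) {
    zm[[paste0(s, "_L")]] <- z[[paste0(s, "_R")]]
    zm[[paste0(s, "_R")]] <- z[[paste0(s, "_L")]]
  }
  subm <- sub
  subm$focus_side <- ifelse(sub$focus_side == "L", "R",
                            ifelse(sub$focus_side == "R", "L", "none"))
  icm <- relabel_laterality(zm, subm)
  expect_equal(icm, ic)
})

test_that("stage ordering is enforced", {
  sub <- make_subjects()
  vol <- data.frame(subject_id = sub$subject_id, anterior_L = rnorm(70, 140, 8))
  z <- set_stage(vol, "z")
  expect_error(adjust_for_etiv(z, sub), "stage")
})
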