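test_that("one-sample t reproduces published summary-statistic examples", {
  r <- one_sample_t(mean = -0.56, sd = 1.01, n = 136)
  expect_equal(round_half_away(r$t, 2), -6.47)
  expect_equal(round_half_away(r$cohen_d, 2), 0.55)
  r2 <- one_sample_t(mean = -0.60, sd = 1.19, n = 136)
  expect_equal(round_half_away(r2$t, 2), -5.88)
  r3 <- one_sample_t(mean = -0.64, sd = 1.22, n = 81)
  expect_equal(round_half_away(r3$t, 2), -4.72)
  expect_equal(round_half_away(r3$cohen_d, 2), 0.52)
})

test_that("summary and raw one-sample t agree exactly; t.test cross-check", {
  set.seed(1)
  x <- rnorm(25, 0.3, 1.2)
  a <- one_sample_t(x)
  b <- one_sample_t(mean = mean(x), sd = sd(x), n = length(x))
  expect_equal(a$t, b$t, tolerance = 1e-12)
  expect_equal(a$p_uncorrected, b$p_uncorrected, tolerance = 1e-12)
  ref <- t.test(x)
  expect_equal(a$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(a$p_uncorrected, ref$p.value, tolerance = 1e-12)
  z <- one_sample_t(c(0, 0, 0))
  expect_equal(c(z$t, z$p_uncorrected, z$cohen_d), c(0, 1, 0))
  expect_error(one_sample_t(c(2, 2, 2)), "sd must be > 0")
})

test_that("paired t equals the one-sample t on differences", {
  set.seed(2)
  a <- rnorm(30); b <- rnorm(30)
  r <- paired_t(a, b)
  ref <- one_sample_t(a - b)
  expect_equal(r$t, ref$t, tolerance = 1e-12)
  expect_equal(r$mean_diff, mean(a - b))
  same <- paired_t(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$mean_diff, 0)
  expect_error(paired_t(a, b[-1]), "length")
})

test_that("independent t matches the textbook pooled computation", {
  a <- c(5.1, 4.8, 5.6, 5.0, 4.7)
  b <- c(4.1, 4.4, 3.9, 4.6)
  sp2 <- (4 * var(a) + 3 * var(b)) / 7
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 5 + 1 / 4))
  r <- independent_t(a, b)
  expect_equal(r$t, t_hand, tolerance = 1e-12)
  expect_equal(r$df, 7)
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(r$p_uncorrected, ref$p.value, tolerance = 1e-12)
  expect_equal(independent_t(a, a)$t, 0)
  expect_error(independent_t(c(1, 1), c(2, 2)), "degenerate")
})

test_that("partial eta squared conversion reproduces printed pairs", {
  expect_equal(round_half_away(partial_eta_from_F(6.30, 1, 204), 2), 0.03)
  expect_equal(round_half_away(partial_eta_from_F(5.30, 3, 77), 2), 0.17)
  expect_equal(partial_eta_from_F(0, 3, 50), 0)
  expect_error(partial_eta_from_F(2, 0, 10), "degrees of freedom")
})

test_that("bonferroni caps at one and is identity for m = 1", {
  expect_equal(bonferroni(0.2, 8), 1)
  expect_equal(bonferroni(0.05, 1), 0.05)
  expect_equal(bonferroni(0.004, 8), 0.032)
  expect_error(bonferroni(0.05, 0), "m must be")
})

test_that("pearson correlation matches cor.test and calibrates under null", {
  set.seed(4)
  x <- rnorm(50); y <- 0.5 * x + rnorm(50)
  r <- pearson_corr(x, y, m = 3)
  ref <- cor.test(x, y)
  expect_equal(r$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(r$p_uncorrected, ref$p.value, tolerance = 1e-12)
  expect_equal(r$p_corrected, min(1, 3 * ref$p.value))
  expect_equal(pearson_corr(x, x)$r, 1)
  rej <- mean(vapply(1:400, function(i) {
    set.seed(1000 + i)
    pearson_corr(rnorm(40), rnorm(40))$p_uncorrected < 0.05
  }, logical(1)))
  expect_gt(rej, 0.02); expect_lt(rej, 0.08)
  expect_error(pearson_corr(x, rep(1, 50)), "zero variance")
})

test_that("mixed ANOVA reports the published df structure", {
  set.seed(6)
  # two groups, eight within levels, N = 206
  Y <- matrix(rnorm(206 * 8), 206, 8)
  g <- rep(c("control", "epilepsy"), c(70, 136))
  res <- mixed_anova_wide(Y, g, 8L, "nuclei")
  w <- res[res$effect == "nuclei" & res$statistic == "wilks", ]
  expect_equal(c(w$df1, w$df2), c(7, 198))
  b <- res[res$effect == "group", ]
  expect_equal(c(b$df1, b$df2), c(1, 204))
  # three groups, 4 nuclei x 2 lateralities, N = 136
  Y2 <- matrix(rnorm(136 * 8), 136, 8)
  g2 <- rep(c("TLE", "FLE", "PQE"), c(81, 36, 19))
  res2 <- mixed_anova_wide(Y2, g2, c(4L, 2L), c("nuclei", "laterality"))
  nuc <- res2[res2$effect == "nuclei" & res2$statistic == "wilks", ]
  expect_equal(c(nuc$df1, nuc$df2), c(3, 131))
  int <- res2[res2$effect == "nuclei:group" & res2$statistic == "pillai", ]
  expect_equal(c(int$df1, int$df2), c(6, 264))
  lat <- res2[res2$effect == "laterality" & res2$statistic == "wilks", ]
  expect_equal(c(lat$df1, lat$df2), c(1, 133))
  expect_equal(res2$partial_eta_sq,
               res2$F * res2$df1 / (res2$F * res2$df1 + res2$df2),
               tolerance = 1e-12)
})

test_that("mixed ANOVA agrees with the independent car implementation", {
  set.seed(12)
  Y <- matrix(rnorm(60 * 8), 60, 8)
  g <- factor(rep(c("a", "b", "c"), c(25, 20, 15)))
  res <- mixed_anova_wide(Y, g, c(4L, 2L), c("nuc", "lat"))
  idata <- expand.grid(lat = factor(c("i", "c"), levels = c("i", "c")),
                       nuc = factor(paste0("n", 1:4)))
  idata <- idata[order(idata$nuc, idata$lat), ]
  mod <- lm(Y ~ g, contrasts = list(g = "contr.sum"))
  av <- car::Anova(mod, idata = idata, idesign = ~ nuc * lat, type = 3)
  s <- suppressWarnings(summary(av, multivariate = TRUE))
  pick <- function(effect, stat) {
    r <- res[res$effect == effect & res$statistic == stat, ]
    c(r$F, r$df1, r$df2, r$p)
  }
  for (map in list(c("nuc", "nuc"), c("g:nuc", "nuc:group"),
                   c("lat", "lat"), c("g:lat", "lat:group"),
                   c("nuc:lat", "nuc:lat"),
                   c("g:nuc:lat", "nuc:lat:group"))) {
    mt <- s$multivariate.tests[[map[1]]]
    out <- capture.output(print(mt))
    for (stat in c("Wilks", "Pillai")) {
      ln <- strsplit(trimws(grep(stat, out, value = TRUE)), "\\s+")[[1]]
      ref <- as.numeric(ln[c(4, 5, 6, 7)])  # F, df1, df2, p
      mine <- pick(map[2], tolower(stat))
      expect_equal(mine, ref, tolerance = 1e-4,
                   label = paste(map[2], stat))
    }
  }
})

test_that("the long-format interface matches the wide computation", {
  set.seed(30)
  n <- 24
  Y <- matrix(rnorm(n * 8), n, 8)
  g <- rep(c("x", "y"), each = n / 2)
  long <- expand.grid(subject = sprintf("s%02d", 1:n),
                      nuclei = paste0("n", 1:4),
                      laterality = c("c1", "c2"), stringsAsFactors = FALSE)
  long$group <- g[match(long$subject, sprintf("s%02d", 1:n))]
  col <- (match(long$nuclei, paste0("n", 1:4)) - 1) * 2 +
    match(long$laterality, c("c1", "c2"))
  long$value <- Y[cbind(match(long$subject, sprintf("s%02d", 1:n)), col)]
  a <- mixed_anova(long, "value", "subject", "group", c("nuclei", "laterality"))
  b <- mixed_anova_wide(Y, g, c(4L, 2L), c("nuclei", "laterality"))
  expect_equal(a$F, b$F, tolerance = 1e-10)
  long2 <- long[-1, ]
  expect_error(mixed_anova(long2, "value", "subject", "group",
                           c("nuclei", "laterality")), "incomplete within")
})

test_that("edgewise maps flag a planted single-edge reduction", {
  cfg <- small_config(seed = 19)
  sub <- generate_cohort(cfg)
  mats <- generate_connectivity(sub, cfg)$matrices
  is_ctrl <- sub$group == "control"
  pats <- mats[!is_ctrl]
  # plant a focal reduction on one edge of every patient
  pats <- lapply(pats, function(m) {
    m["Thal_Pulvinar_L", "Lingual_Gyrus_L"] <- m["Thal_Pulvinar_L", "Lingual_Gyrus_L"] - 0.5
    m["Lingual_Gyrus_L", "Thal_Pulvinar_L"] <- m["Thal_Pulvinar_L", "Lingual_Gyrus_L"]
    m
  })
  mp <- edgewise_map(pats, mats[is_ctrl], "pulvinar", "L")
  expect_equal(nrow(mp), 121)
  expect_equal(mp$target[which.min(mp$t)], "Lingual_Gyrus_L")
  same <- edgewise_map(mats[is_ctrl], mats[is_ctrl], "pulvinar", "L")
  expect_lt(max(abs(same$t)), 1e-10)
})

test_that("control profiles rank the planted strongest connection first", {
  cfg <- small_config(seed = 23)
  sub <- generate_cohort(cfg)
  mats <- generate_connectivity(sub, cfg)$matrices[sub$group == "control"]
  ctrl_sub <- sub[sub$group == "control", ]
  prof <- control_profile(mats, "anterior", subjects = ctrl_sub, top_k = 10)
  expect_equal(nrow(prof), 10)
  expect_equal(prof$target[1], "Amygdala")
  expect_true("Hippocampus" %in% prof$target[1:3])
  # two identical hemispheres: averaging is the identity
  msym <- population_mean_matrix()
  msym2 <- (msym + mirror_matrix(msym)) / 2
  p2 <- control_profile(list(a = msym2, b = msym2), "pulvinar", top_k = Inf)
  raw <- extract_thalamic_edges(msym2, "pulvinar", "L")
  expect_equal(p2$value[p2$target == "Hippocampus"],
               raw$value[raw$target == "Hippocampus_L"])
})
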