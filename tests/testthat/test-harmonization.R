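# Simulated two-batch tables following the location/scale model the
# harmonization assumes: y = intercept + age*slope + batch offset +
# batch-scaled noise. Closed-form expectations follow directly.

sim_batch_table <- function(n_per = 200, p = 40, offset = 0.1, scale = 1,
                            age_slope = 0.1, seed = 11) {
  set.seed(seed)
  n <- 2 * n_per
  batch <- rep(c("A", "B"), each = n_per)
  age <- runif(n, 5, 18)
  noise <- matrix(rnorm(n * p), n, p)
  sel <- batch == "B"
  noise[sel, ] <- noise[sel, ] * scale
  x <- outer(age - 11.5, rep(age_slope, p)) + noise
  x[sel, ] <- x[sel, ] + offset
  colnames(x) <- sprintf("f%02d", seq_len(p))
  list(x = x, batch = batch, age = age)
}

test_that("additive offset appears in the batch location estimates", {
  d <- sim_batch_table(n_per = 800, p = 60, offset = 0.1, scale = 1,
                       age_slope = 0)
  fit <- combat_fit(d$x, d$batch)
  gap <- (fit$gamma_star["B", ] - fit$gamma_star["A", ]) * fit$sigma_hat
  expect_lt(abs(mean(gap) - 0.1), 0.02)
})

test_that("a single batch yields gamma* ~ 0 and delta* ~ 1", {
  d <- sim_batch_table()
  fit <- combat_fit(d$x[d$batch == "A", ], rep("A", sum(d$batch == "A")))
  expect_lt(max(abs(fit$gamma_star)), 1e-10)
  expect_equal(unname(fit$delta_star["A", ]), rep(1, 40), tolerance = 0.05)
  # applying a single-batch model to its own data is near the identity;
  # the residual reflects only the n/(n-1) convention gap between the
  # pooled and per-batch variance estimators
  out <- combat_apply(d$x[d$batch == "A", ], rep("A", sum(d$batch == "A")), fit)
  expect_lt(max(abs(out - d$x[d$batch == "A", ])) / sd(d$x), 0.02)
})

test_that("a planted scale shows up as the squared variance ratio", {
  d <- sim_batch_table(offset = 0, scale = 1.5, age_slope = 0, n_per = 400)
  fit <- combat_fit(d$x, d$batch)
  ratio <- fit$delta_star["B", ] / fit$delta_star["A", ]
  expect_equal(mean(ratio), 2.25, tolerance = 0.15)
})

test_that("harmonization equalizes batch means and preserves age effects", {
  d <- sim_batch_table(offset = 0.1, scale = 1.5, age_slope = 0.1,
                       n_per = 400, p = 60)
  cov <- data.frame(age = d$age)
  fit <- combat_fit(d$x, d$batch, cov)
  adj <- combat_apply(d$x, d$batch, fit, cov)
  gap_pre <- abs(colMeans(d$x[d$batch == "B", ]) -
                   colMeans(d$x[d$batch == "A", ]))
  gap <- abs(colMeans(adj[d$batch == "B", ]) - colMeans(adj[d$batch == "A", ]))
  expect_lt(mean(gap / fit$sigma_hat), 0.05)
  expect_lt(mean(gap), mean(gap_pre) / 2)
  # age effect: unbiased across features and barely moved per feature
  slope <- function(tab) apply(tab, 2, function(y) coef(lm(y ~ d$age))[2])
  s_pre <- slope(d$x); s_post <- slope(adj)
  expect_lt(abs(mean(s_post) - 0.1) / 0.1, 0.05)
  expect_lt(mean(abs(s_post - s_pre)) / 0.1, 0.05)
})

test_that("re-harmonizing already harmonized data changes little", {
  # Exact idempotence cannot hold: the second pass re-estimates the scale
  # standardization from the transformed data, so residual changes are of
  # the order of the shrinkage/sampling residual, not zero. The contract
  # is that a second pass moves values by a small fraction of the first
  # pass's correction.
  d <- sim_batch_table(offset = 0.3, scale = 1.3, n_per = 150, p = 30)
  cov <- data.frame(age = d$age)
  for (eb in c(FALSE, TRUE)) {
    fit1 <- combat_fit(d$x, d$batch, cov, eb = eb)
    h1 <- combat_apply(d$x, d$batch, fit1, cov)
    first_move <- mean(abs(h1 - d$x))
    fit2 <- combat_fit(h1, d$batch, cov, eb = eb)
    h2 <- combat_apply(h1, d$batch, fit2, cov)
    expect_lt(mean(abs(h2 - h1)) / first_move, 0.2)
    rep2 <- harmonization_report(h1, h2, d$batch)
    expect_lt(max(rep2$post_fraction), 0.02)
  }
})

test_that("report shows reduced between-batch variance fractions", {
  d <- sim_batch_table(offset = 0.3, scale = 1.5, n_per = 400, p = 50)
  fit <- combat_fit(d$x, d$batch)
  adj <- combat_apply(d$x, d$batch, fit)
  rep_ <- harmonization_report(d$x, adj, d$batch)
  expect_gte(mean(rep_$post_fraction < rep_$pre_fraction), 0.95)
  same <- harmonization_report(d$x, d$x, d$batch)
  expect_equal(same$pre_fraction, same$post_fraction)
  d0 <- sim_batch_table(offset = 0, scale = 1)
  rep0 <- harmonization_report(d0$x, d0$x, d0$batch)
  expect_lt(max(rep0$pre_fraction), 0.05)
  expect_error(harmonization_report(d$x, d$x[-1, ], d$batch), "shapes")
})

test_that("zero-variance features warn and pass through unchanged", {
  d <- sim_batch_table(p = 10)
  d$x[, 3] <- 5
  expect_warning(fit <- combat_fit(d$x, d$batch), "zero-variance")
  adj <- combat_apply(d$x, d$batch, fit)
  expect_equal(adj[, 3], d$x[, 3])
})

test_that("errors: tiny batch, unseen batch label, confounded covariate", {
  d <- sim_batch_table(p = 5, n_per = 50)
  expect_error(combat_fit(d$x[1:51, ], c(rep("A", 50), "B")), "fewer than 2")
  fit <- combat_fit(d$x, d$batch)
  expect_error(combat_apply(d$x, rep("C", nrow(d$x)), fit), "unseen batch")
  expect_error(combat_fit(d$x, d$batch,
                          data.frame(isB = as.numeric(d$batch == "B"))),
               "confounded")
})

test_that("implementation agrees with the reference ComBat (sva)", {
  d <- sim_batch_table(offset = 0.2, scale = 1.4, n_per = 80, p = 25, seed = 4)
  cov <- data.frame(age = d$age)
  fit <- combat_fit(d$x, d$batch, cov)
  mine <- combat_apply(d$x, d$batch, fit, cov)
  ref <- t(sva::ComBat(dat = t(d$x), batch = d$batch,
                       mod = model.matrix(~ d$age), par.prior = TRUE))
  expect_equal(unname(mine), unname(ref), tolerance = 1e-6)
})

test_that("matrix-set harmonization removes edge batch effects, keeps symmetry", {
  cfg <- small_config(seed = 13)
  sub <- generate_cohort(cfg)
  mats <- generate_connectivity(sub, cfg)$matrices
  ut <- upper.tri(mats[[1]])
  edges <- t(vapply(mats, function(m) m[ut], numeric(sum(ut))))
  edges <- inject_batch_effects(edges, sub$scanner_batch, "batch_3T",
                                additive = 0.1)
  labs <- rownames(mats[[1]])
  dirty <- lapply(seq_along(mats), function(s) {
    m <- matrix(0, 122, 122, dimnames = list(labs, labs))
    m[ut] <- edges[s, ]; m <- m + t(m); diag(m) <- 1
    m
  })
  names(dirty) <- sub$subject_id
  hm <- harmonize_matrices(dirty, sub$scanner_batch,
                           data.frame(age = sub$age))
  m1 <- hm$matrices[[1]]
  expect_equal(m1, t(m1))
  expect_equal(diag(m1), setNames(rep(1, 122), labs))
  post <- t(vapply(hm$matrices, function(m) m[ut], numeric(sum(ut))))
  gap_pre <- abs(colMeans(edges[sub$scanner_batch == "batch_3T", ]) -
                   colMeans(edges[sub$scanner_batch == "batch_1p5T", ]))
  gap_post <- abs(colMeans(post[sub$scanner_batch == "batch_3T", ]) -
                    colMeans(post[sub$scanner_batch == "batch_1p5T", ]))
  expect_gt(mean(gap_post < gap_pre), 0.90)
})
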