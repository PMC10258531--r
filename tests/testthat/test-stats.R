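# stats module: Welch t, mixed ANOVA/ANCOVA, sphericity, BH post-hocs

test_that("welch_t matches the base t.test oracle", {
  set.seed(1)
  for (rep in 1:5) {
    a <- rnorm(sample(5:30, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(5:30, 1), mean = runif(1, -1, 1))
    mine <- welch_t(a, b)
    ref <- t.test(a, b)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-12)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  }
  # identical samples: t exactly 0
  x <- c(1, 2, 3, 4)
  expect_equal(welch_t(x, x)$t, 0)
  expect_error(welch_t(c(1, 1), c(2, 2)), class = "degenerate_test")
  expect_error(welch_t(1, c(1, 2)), class = "invalid_parameter")
})

test_that("between-only ANOVA F equals the squared pooled-variance t", {
  set.seed(2)
  d <- data.frame(participant = sprintf("p%02d", 1:20),
                  g = rep(c("A", "B"), each = 10),
                  onset = "x",
                  value = rnorm(20, rep(c(0, 0.8), each = 10)))
  a <- mixed_anova(d, "value", within = NULL, between = "g")
  tp <- t.test(value ~ g, d, var.equal = TRUE)
  expect_equal(a$effects$F[a$effects$effect == "g"],
               unname(tp$statistic)^2, tolerance = 1e-8)
  expect_equal(a$effects$p[a$effects$effect == "g"], tp$p.value,
               tolerance = 1e-8)
})

test_that("mixed ANOVA reproduces the multivariate-model oracle (balanced)", {
  set.seed(3)
  cells <- expand.grid(diagnosis = c("MD", "HC"), onset = c("early", "late"),
                       stringsAsFactors = FALSE)
  dat <- do.call(rbind, lapply(1:4, function(i)
    do.call(rbind, lapply(1:6, function(j)
      data.frame(participant = sprintf("c%d_%d", i, j),
                 diagnosis = cells$diagnosis[i], onset = cells$onset[i],
                 roi = paste0("r", 1:4),
                 value = rnorm(4, c(1, 1.1, 0.9, 1.3), c(.2, .3, .5, .9)) +
                   rnorm(1, 0, .3))))))
  res <- mixed_anova(dat, "value", within = "roi",
                     between = c("diagnosis", "onset"))

  wide <- dat[dat$roi == "r1", c("participant", "diagnosis", "onset")]
  Y <- sapply(paste0("r", 1:4), function(r) dat$value[dat$roi == r])
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  fit <- lm(Y ~ diagnosis * onset, data = wide)
  idata <- data.frame(roi = factor(paste0("r", 1:4)))
  a <- anova(fit, M = ~roi, X = ~1, idata = idata, test = "Spherical")
  # balanced design: sequential == Type III, so every within F must agree
  eff <- res$effects
  expect_equal(eff$F[eff$effect == "roi"], a$F[1], tolerance = 1e-9)
  expect_equal(eff$F[eff$effect == "diagnosis:roi"], a$F[2],
               tolerance = 1e-9)
  expect_equal(eff$F[eff$effect == "onset:roi"], a$F[3], tolerance = 1e-9)
  expect_equal(eff$F[eff$effect == "diagnosis:onset:roi"], a$F[4],
               tolerance = 1e-9)
  # HF-corrected p-values and the epsilons
  p_col <- if (eff$correction[eff$effect == "roi"] == "HF") "H-F Pr"
           else "Pr(>F)"
  expect_equal(eff$p[eff$effect == "roi"], a[1, p_col], tolerance = 1e-6)
  mt <- mauchly.test(fit, M = ~roi, X = ~1, idata = idata)
  expect_equal(res$mauchly_W, unname(mt$statistic), tolerance = 1e-9)
  # base R's second-order term carries a known typo; agree to ~1e-3
  expect_equal(res$mauchly_p, mt$p.value, tolerance = 2e-3)
  # between stratum against a direct Type III drop-column refit
  yb <- rowMeans(Y)
  X <- model.matrix(~ diagnosis * onset, wide)
  sse <- sum(qr.resid(qr(X), yb)^2)
  for (nm in c("diagnosis1", "onset1", "diagnosis1:onset1")) {
    ss <- sum(qr.resid(qr(X[, setdiff(colnames(X), nm)]), yb)^2) - sse
    f_oracle <- ss / (sse / (nrow(X) - ncol(X)))
    lab <- sub("1$", "", sub("1:", ":", nm))
    expect_equal(eff$F[eff$effect == lab], f_oracle, tolerance = 1e-9)
  }
})

test_that("two-level within factors need no sphericity machinery", {
  tab <- sim_metric_table(4, k_within = 2, seed = 4)
  res <- mixed_anova(tab, "value", within = "roi_label",
                     between = c("diagnosis", "onset"))
  expect_true(is.na(res$mauchly_W))
  expect_true(all(res$effects$correction == "none"))
  expect_equal(nrow(res$effects), 7)
})

test_that("constant dv is flagged instead of crashing", {
  tab <- sim_metric_table(3, k_within = 2, seed = 5)
  tab$value <- 1
  res <- mixed_anova(tab, "value", within = "roi_label",
                     between = c("diagnosis", "onset"))
  expect_true(res$flagged_constant)
  expect_true(all(is.na(res$effects$F) | res$effects$F < 1e-10))
})

test_that("missing within-levels abort with the participant named", {
  tab <- sim_metric_table(3, k_within = 2, seed = 6)
  tab <- tab[!(tab$participant == "p005" & tab$roi_label == "roi2"), ]
  err <- expect_error(
    mixed_anova(tab, "value", within = "roi_label",
                between = c("diagnosis", "onset")),
    class = "unbalanced_design")
  expect_match(conditionMessage(err), "p005")
})

test_that("mauchly_and_hf handles the canonical covariance shapes", {
  # compound symmetry: perfect sphericity
  S <- matrix(0.3, 4, 4); diag(S) <- 1
  r <- mauchly_and_hf(S, n = 20, k = 4)
  expect_equal(r$W, 1, tolerance = 1e-12)
  expect_equal(r$epsilon_gg, 1, tolerance = 1e-12)
  expect_equal(r$epsilon_hf, 1)

  # maximally non-spherical toy: eigenvalue-formula oracle
  S2 <- diag(c(1, 1, 100))
  r2 <- mauchly_and_hf(S2, n = 20, k = 3)
  M <- vf2cortex:::orthonormal_contrasts(3)
  ev <- eigen(t(M) %*% S2 %*% M, symmetric = TRUE)$values
  expect_equal(r2$W, prod(ev) / mean(ev)^2, tolerance = 1e-12)
  expect_equal(r2$epsilon_gg, sum(ev)^2 / (2 * sum(ev^2)), tolerance = 1e-12)
  expect_lt(r2$epsilon_gg, 0.55)   # near the 1/(k-1) lower bound

  # property: eps_HF >= eps_GG over random covariances
  set.seed(7)
  for (i in 1:20) {
    A <- matrix(rnorm(25), 5)
    r3 <- mauchly_and_hf(crossprod(A) + diag(5), n = 15, k = 5)
    expect_gte(r3$epsilon_hf + 1e-12, r3$epsilon_gg)
    expect_true(r3$W >= 0 && r3$W <= 1 + 1e-12)
  }
  expect_error(mauchly_and_hf(matrix(1, 3, 3), n = 10, k = 3),
               class = "singular_matrix")
  expect_error(mauchly_and_hf(diag(2), n = 10, k = 2),
               class = "invalid_parameter")
})

test_that("covariates behave: absorption, detection, and failure modes", {
  # an uncorrelated covariate barely changes the effect tests
  tab <- sim_metric_table(20, k_within = 2, seed = 8,
                          effects = list(diagnosis = 1))
  cov_df <- data.frame(participant = unique(tab$participant))
  set.seed(9)
  cov_df$junk <- rnorm(nrow(cov_df))
  tab2 <- merge(tab, cov_df, by = "participant")
  a0 <- mixed_anova(tab2, "value", within = "roi_label",
                    between = c("diagnosis", "onset"))
  a1 <- mixed_ancova(tab2, "value", within = "roi_label",
                     between = c("diagnosis", "onset"),
                     covariates = "junk")
  f0 <- a0$effects$F[a0$effects$effect == "diagnosis"]
  f1 <- a1$effects$F[a1$effects$effect == "diagnosis"]
  expect_equal(f1, f0, tolerance = 0.15)

  # dv driven by the covariate: covariate F large, groups stay null
  set.seed(10)
  cov_df$drive <- rnorm(nrow(cov_df))
  tab3 <- merge(sim_metric_table(20, k_within = 2, seed = 11), cov_df)
  tab3$value <- tab3$value * 0.05 + 2 * tab3$drive
  a2 <- mixed_ancova(tab3, "value", within = "roi_label",
                     between = c("diagnosis", "onset"),
                     covariates = "drive")
  expect_lt(a2$effects$p[a2$effects$effect == "drive"], 1e-6)
  expect_gt(a2$effects$p[a2$effects$effect == "diagnosis"], 0.01)

  # zero-variance covariate -> collinearity error
  cov_df$flat <- 1
  tab4 <- merge(tab, cov_df)
  expect_error(mixed_ancova(tab4, "value", within = "roi_label",
                            between = c("diagnosis", "onset"),
                            covariates = "flat"),
               class = "collinearity")
  # covariate varying within participant is rejected
  tab5 <- tab2
  tab5$junk <- seq_len(nrow(tab5))
  expect_error(mixed_ancova(tab5, "value", within = "roi_label",
                            between = c("diagnosis", "onset"),
                            covariates = "junk"),
               class = "invalid_parameter")
})

test_that("prepare_covariates log-centers eccentricity and centers size", {
  df <- data.frame(ecc = c(2, 4, 8), size = c(50, 100, 150))
  out <- prepare_covariates(df, ecc = "ecc", size = "size")
  expect_equal(out$ecc_logc, log(df$ecc) - mean(log(df$ecc)))
  expect_equal(out$size_c, c(-50, 0, 50))
  expect_equal(mean(out$ecc_logc), 0)
})

test_that("ANOVA p for diagnosis agrees with a permutation-label null", {
  tab <- sim_metric_table(6, k_within = 2, seed = 12,
                          effects = list(diagnosis = 0.9))
  obs <- mixed_anova(tab, "value", within = "roi_label",
                     between = c("diagnosis", "onset"))
  f_obs <- obs$effects$F[obs$effects$effect == "diagnosis"]
  p_obs <- obs$effects$p[obs$effects$effect == "diagnosis"]
  ids <- unique(tab$participant)
  set.seed(13)
  f_perm <- replicate(2000, {
    relab <- setNames(sample(tab$diagnosis[match(ids, tab$participant)]), ids)
    t2 <- tab
    t2$diagnosis <- relab[t2$participant]
    a <- mixed_anova(t2, "value", within = "roi_label",
                     between = c("diagnosis", "onset"))
    a$effects$F[a$effects$effect == "diagnosis"]
  })
  p_perm <- mean(f_perm >= f_obs)
  mc_err <- 3 * sqrt(p_perm * (1 - p_perm) / 2000) + 0.02
  expect_lt(abs(p_perm - p_obs), mc_err + 0.02)
})

test_that("BH adjustment matches its definition and stats::p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  set.seed(14)
  for (i in 1:10) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), p.adjust(p, "BH"), tolerance = 1e-12)
  }
  # monotone in the raw-p ordering
  p <- runif(30)
  adj <- bh_adjust(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
})

test_that("posthoc_fdr runs Welch tests per ROI under one BH family", {
  tab <- sim_metric_table(10, k_within = 4, seed = 15,
                          effects = list(diagnosis = 2))
  ph <- posthoc_fdr(tab, "value", "diagnosis")
  expect_equal(nrow(ph), 4)
  expect_equal(ph$p_adj, bh_adjust(ph$p))
  # single ROI: adjusted equals raw
  one <- posthoc_fdr(tab[tab$roi_label == "roi1", ], "value", "diagnosis")
  expect_equal(one$p_adj, one$p)
  # all raw p near 1 -> nothing significant
  null_tab <- sim_metric_table(10, k_within = 3, seed = 16)
  ph0 <- posthoc_fdr(null_tab, "value", "diagnosis")
  expect_true(all(ph0$p_adj >= ph0$p))
  # oracle: each row equals a direct welch_t on that ROI's values
  sel <- tab$roi_label == "roi2"
  ref <- welch_t(tab$value[sel & tab$diagnosis == "HC"],
                 tab$value[sel & tab$diagnosis == "MD"])
  expect_equal(ph$t[ph$roi == "roi2"], ref$t)
})
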