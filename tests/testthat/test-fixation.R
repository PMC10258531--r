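# fixation module: PRL center, BCEA, overlay, trimming, URL placement

test_that("compute_prl_center is the coordinate mean", {
  one <- fixation_cloud(matrix(c(2, -3), 1), "left")
  expect_equal(unname(compute_prl_center(one)), c(2, -3))
  # symmetric cloud about (5, 0)
  sym <- fixation_cloud(rbind(c(4, 1), c(6, -1), c(5, 2), c(5, -2)), "left")
  expect_equal(unname(compute_prl_center(sym)), c(5, 0))
  # brute-force oracle on a random cloud
  set.seed(1)
  pts <- matrix(rnorm(2000), ncol = 2)
  cl <- fixation_cloud(pts, "right")
  expect_equal(unname(compute_prl_center(cl)), unname(colMeans(pts)))
  expect_error(compute_prl_center(fixation_cloud(pts[0, , drop = FALSE], "left")),
               class = "empty_input")
})

test_that("fit_bcea matches the closed form and its invariances", {
  set.seed(2)
  pts <- matrix(rnorm(2e5), ncol = 2)
  cl <- fixation_cloud(pts, "left")
  b <- fit_bcea(cl, 0.63)
  # area ~ pi * (-2 log 0.37) for unit-variance circular clouds
  expect_equal(b$area_deg2, pi * qchisq(0.63, 2), tolerance = 0.02)
  expect_equal(b$chi2_quantile, -2 * log(0.37), tolerance = 1e-6)

  # quadratic scaling: doubling coordinates quadruples the area exactly
  b2 <- fit_bcea(fixation_cloud(2 * pts, "left"), 0.63)
  expect_equal(b2$area_deg2, 4 * b$area_deg2, tolerance = 1e-12)

  # rotation and translation invariance of the area
  set.seed(3)
  pts2 <- matrix(rnorm(600), ncol = 2) %*% matrix(c(1, .4, 0, .8), 2)
  R <- vf2cortex:::rot2(33)
  a0 <- fit_bcea(fixation_cloud(pts2, "left"), 0.63)$area_deg2
  a1 <- fit_bcea(fixation_cloud(pts2 %*% t(R), "left"), 0.63)$area_deg2
  a2 <- fit_bcea(fixation_cloud(sweep(pts2, 2, c(-7, 11)), "left"),
                 0.63)$area_deg2
  expect_equal(a1, a0, tolerance = 1e-9)
  expect_equal(a2, a0, tolerance = 1e-9)

  # 95% ellipse strictly larger than 63% for non-degenerate clouds
  expect_gt(fit_bcea(fixation_cloud(pts2, "left"), 0.95)$area_deg2, a0)

  # degenerate cloud: zero area, flagged
  same <- fixation_cloud(matrix(1, 5, 2), "left")
  expect_warning(bd <- fit_bcea(same, 0.63), "degenerate")
  expect_equal(bd$area_deg2, 0)
  expect_true(bd$degenerate)
})

test_that("BCEA ellipses cover the stated fraction of fixations", {
  # Monte-Carlo coverage oracle at both conventional levels
  set.seed(4)
  pts <- matrix(rnorm(2e5, sd = 1.3), ncol = 2)
  cl <- fixation_cloud(pts, "left")
  for (P in c(0.63, 0.95)) {
    b <- fit_bcea(cl, P)
    S <- cov(pts)
    d <- sweep(pts, 2, b$center)
    inside <- rowSums((d %*% solve(S)) * d) <= b$chi2_quantile
    expect_equal(mean(inside), P, tolerance = 0.01)
  }
})

test_that("select_bcea_level applies the eccentricity rule with its tie", {
  expect_equal(select_bcea_level(2, 7), 0.63)
  expect_equal(select_bcea_level(12, 7), 0.95)
  expect_equal(select_bcea_level(7, 7), 0.63)  # documented tie rule
})

test_that("overlay_eyes takes the OR of seen flags and max threshold", {
  l <- gen_sensitivity_map(0, seed = 1, eye = "left")
  r <- gen_sensitivity_map(0, seed = 1, eye = "right")
  fused <- overlay_eyes(l, r)
  expect_identical(fused$seen, l$seen)
  expect_equal(fused$threshold_db, pmax(l$threshold_db, r$threshold_db))

  blind <- gen_sensitivity_map(100, seed = 2, eye = "left")
  fused2 <- overlay_eyes(blind, r)
  expect_true(all(fused2$seen))

  # complementary half-field blindness -> fully seen; per-locus OR oracle
  lh <- l; rh <- r
  lh$seen <- lh$x_deg < 0; rh$seen <- rh$x_deg >= 0
  f3 <- overlay_eyes(lh, rh)
  expect_identical(f3$seen, lh$seen | rh$seen)
  expect_true(all(f3$seen))
})

test_that("trim_to_seeing removes bilateral-scotoma cells and is idempotent", {
  fused <- seeing_map()
  roi <- disc_roi(c(8, 0), 2)
  expect_identical(trim_to_seeing(roi, fused)$mask, roi$mask)

  # ROI entirely inside a bilateral scotoma errors
  blind <- overlay_eyes(gen_sensitivity_map(100, seed = 1, eye = "left"),
                        gen_sensitivity_map(100, seed = 2, eye = "right"))
  expect_error(trim_to_seeing(roi, blind), class = "empty_roi")

  # half-plane scotoma on a dense lattice (loci offset from y = 0 so the
  # boundary bisects the ROI cleanly): area halves (cell-count oracle)
  lat <- expand.grid(x_deg = seq(6.25, 13.75, by = 0.5),
                     y_deg = seq(-3.75, 3.75, by = 0.5))
  half <- sensitivity_map(data.frame(lat, threshold_db = 30,
                                     seen = lat$y_deg > 0), eye = "fused")
  roi0 <- disc_roi(c(10, 0), 3)
  tr <- trim_to_seeing(roi0, half)
  cells <- roi_cells(roi0)
  keep_oracle <- half$seen[vf2cortex:::nearest_locus(cells, half)]
  expect_equal(roi_area(tr), sum(keep_oracle) * roi0$step^2)
  expect_equal(roi_area(tr) / roi_area(roi0), 0.5, tolerance = 0.1)
  # idempotent
  expect_identical(trim_to_seeing(tr, half)$mask, tr$mask)
})

test_that("place_url prefers the vertical flip under uniform vision", {
  # uniform: every locus seen with the same threshold, so all symmetric
  # candidates tie and the documented preference order decides
  fused <- seeing_map()
  fused$threshold_db <- 30
  prl <- disc_roi(c(5, 0), 1.5)
  url <- place_url(prl, fused)
  expect_equal(url$meta$url_transform, "vflip")
  expect_equal(roi_center(url), c(-5, 0), tolerance = 1e-9)
  expect_equal(roi_area(url), roi_area(prl))
  expect_equal(roi_eccentricity(url), roi_eccentricity(prl),
               tolerance = 1e-6)
})

test_that("URL candidates all preserve eccentricity; scoring matches brute force", {
  fused <- seeing_map()
  fused$seen <- fused$x_deg > 0.1   # blind left hemifield
  prl <- disc_roi(c(5, 0), 1.5)
  url <- place_url(prl, fused, n_candidates = 36)
  expect_equal(roi_eccentricity(url), roi_eccentricity(prl),
               tolerance = 1e-6)
  expect_false(url$meta$url_transform %in% "vflip")
  # winner must be in the right hemifield
  expect_gt(roi_center(url)[1], 0)

  # exhaustive candidate scan oracle
  score_oracle <- function(R) {
    z <- cbind(fused$x_deg, fused$y_deg) %*% R
    i <- floor((z[, 1] - prl$origin[1]) / prl$step) + 1
    j <- floor((z[, 2] - prl$origin[2]) / prl$step) + 1
    ok <- i >= 1 & i <= prl$dim[1] & j >= 1 & j <= prl$dim[2]
    inside <- ok
    inside[ok] <- prl$mask[(j[ok] - 1) * prl$dim[1] + i[ok]]
    sum(inside & fused$seen)
  }
  cands <- c(list(diag(c(-1, 1)), diag(c(1, -1))),
             lapply((1:35) * 10, vf2cortex:::rot2))
  best <- max(vapply(cands, score_oracle, numeric(1)))
  expect_equal(score_oracle(url$R), best)

  # no candidate with vision at all -> dedicated error
  none <- fused; none$seen <- FALSE
  expect_error(place_url(prl, none), class = "no_valid_url")
})

test_that("roi_eccentricity is a fovea distance in degrees", {
  expect_equal(roi_eccentricity(c(0, 0)), 0)
  expect_equal(roi_eccentricity(c(3, 4)), 5)
  expect_equal(roi_eccentricity(c(30, 40), px_per_deg = 10), 5)
  # rotation about the fovea leaves it unchanged
  p <- c(3, 4)
  for (a in c(10, 77, 191))
    expect_equal(roi_eccentricity(as.numeric(vf2cortex:::rot2(a) %*% p)), 5)
})

test_that("ingest converts pixels and applies the retinal flip", {
  px <- rbind(c(110, 95), c(90, 105))
  cl <- fixation_cloud(px, "left", fovea = c(100, 100), px_per_deg = 10)
  expect_equal(unname(cl$points), rbind(c(1, -0.5), c(-1, 0.5)))
  flipped <- fixation_cloud(px, "left", fovea = c(100, 100),
                            px_per_deg = 10, flip = TRUE)
  expect_equal(unname(flipped$points), -unname(cl$points))
})
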