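# Synthetic study generator: fixation clouds, sensitivity grids, metric maps
# and full cohorts with a 2x2 (diagnosis x onset) between-participant design.

#' Cohort specification for the synthetic generator
#'
#' Effect-knob convention: every effect is injected as a sum-to-zero cell
#' deflection of half its magnitude, so each knob equals the marginal
#' contrast it creates. `effect_diagnosis = e` deflects MD cells by `+e/2`
#' and control cells by `-e/2` (MD minus control group difference is exactly
#' `e`); `effect_onset_x_diagnosis = e` deflects cells by
#' `(e/2) * s_diag * s_onset` (s = +-1), so the early-minus-late difference
#' within an arm is `e` and the difference-of-differences is `2e`. Thickness
#' deflections are expressed in normalized-thickness units and scaled by the
#' reference thickness (2.1 mm) on the raw scale.
#'
#' @param n_per_cell participants per (diagnosis x onset) cell (>= 2).
#' @param effect_diagnosis MD-minus-control normalized-thickness offset.
#' @param effect_onset_x_diagnosis diagnosis-by-onset interaction deflection
#'   (see convention above).
#' @param noise_sd vertex-level Gaussian noise SD, normalized units.
#' @param participant_sd SD of the participant-level regional offset
#'   (between-participant variance surviving normalization).
#' @param seed RNG seed for the whole cohort.
#' @param scotoma_radius_deg radius of the central scotoma of MD eyes.
#' @param prl_ecc_deg,prl_sd_deg PRL placement distribution (degrees);
#'   defaults match the observed cohort mean of ~9.7 deg with SD ~4.2 deg.
#' @param effect_diagnosis_ficvf,effect_onset_x_diagnosis_ficvf,noise_sd_ficvf,participant_sd_ficvf
#'   analogous knobs for neurite density (FICVF).
#' @param effect_diagnosis_odi,effect_onset_x_diagnosis_odi,noise_sd_odi,participant_sd_odi
#'   analogous knobs for orientation dispersion (ODI).
#' @param n_fixations fixation samples per eye.
#' @param fix_sigma_deg,hc_fix_sigma_deg fixation scatter SD for MD and
#'   control participants.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_cell = 5,
                        effect_diagnosis = -0.03,
                        effect_onset_x_diagnosis = -0.02,
                        noise_sd = 0.08,
                        participant_sd = 0.02,
                        seed = 1L,
                        scotoma_radius_deg = 5,
                        prl_ecc_deg = 9.7, prl_sd_deg = 4.2,
                        effect_diagnosis_ficvf = -0.01,
                        effect_onset_x_diagnosis_ficvf = 0,
                        noise_sd_ficvf = 0.03,
                        participant_sd_ficvf = 0.01,
                        effect_diagnosis_odi = 0,
                        effect_onset_x_diagnosis_odi = 0,
                        noise_sd_odi = 0.02,
                        participant_sd_odi = 0.01,
                        n_fixations = 500,
                        fix_sigma_deg = 1.4, hc_fix_sigma_deg = 0.5) {
  check_number(n_per_cell, "n_per_cell", lower = 2)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(participant_sd, "participant_sd", lower = 0)
  check_number(scotoma_radius_deg, "scotoma_radius_deg", lower = 0)
  check_number(prl_ecc_deg, "prl_ecc_deg", lower = 0)
  check_number(prl_sd_deg, "prl_sd_deg", lower = 0)
  check_number(n_fixations, "n_fixations", lower = 3)
  out <- as.list(environment())
  out$n_per_cell <- as.integer(n_per_cell)
  structure(out, class = "cohort_spec")
}

#' Generate a bivariate-normal fixation cloud
#'
#' @param center field-degree center `(x, y)`.
#' @param sigma_h,sigma_v horizontal/vertical SD in degrees (>= 0).
#' @param rho correlation, |rho| < 1.
#' @param n number of fixations (>= 3).
#' @param seed RNG seed.
#' @param eye which eye the cloud belongs to.
#' @return A [fixation_cloud()].
#' @export
gen_fixations <- function(center = c(0, 0), sigma_h = 1, sigma_v = 1,
                          rho = 0, n = 500, seed = NULL,
                          eye = c("left", "right")) {
  check_number(sigma_h, "sigma_h", lower = 0)
  check_number(sigma_v, "sigma_v", lower = 0)
  check_number(rho, "rho")
  check_number(n, "n", lower = 3)
  if (abs(rho) >= 1)
    vf_stop("invalid_parameter", "|rho| must be < 1")
  # lower-triangular factor of the covariance; valid for zero sigmas too
  A <- matrix(c(sigma_h, 0, rho * sigma_v, sqrt(1 - rho^2) * sigma_v), 2, 2)
  z <- with_seed(seed, matrix(stats::rnorm(2 * n), ncol = 2))
  pts <- sweep(z %*% t(A), 2L, -as.numeric(center))
  fixation_cloud(pts, eye = match.arg(eye))
}

# canonical 65-locus radial grid: center + five rings with 8,16,16,16,8
# loci (a stand-in layout; only the count is conventional). Default ring
# radii reach 18 deg so the grid covers the eccentricity range where PRLs
# are observed (up to ~20 deg).
grid_layout <- function(n_loci = 65, rings = c(2, 6, 10, 14, 18)) {
  counts <- if (n_loci == 65 && length(rings) == 5L)
    c(8L, 16L, 16L, 16L, 8L) else {
    k <- max(0L, as.integer(n_loci) - 1L)
    nr <- length(rings)
    base <- rep(k %/% nr, nr)
    extra <- k - sum(base)
    if (extra > 0) base[seq_len(extra)] <- base[seq_len(extra)] + 1L
    base
  }
  xs <- 0; ys <- 0
  for (i in seq_along(rings)) {
    if (counts[i] == 0L) next
    a <- deg2rad(seq(0, 360, length.out = counts[i] + 1L)[-(counts[i] + 1L)])
    xs <- c(xs, rings[i] * cos(a))
    ys <- c(ys, rings[i] * sin(a))
  }
  data.frame(x_deg = round(xs, 10), y_deg = round(ys, 10))
}

#' Generate a synthetic sensitivity map
#'
#' Radial grid of test loci centered on the fovea (default 65: one central
#' locus plus rings at 2, 6, 10, 14 and 18 degrees, covering the
#' eccentricity range where PRLs occur). Loci with eccentricity strictly
#' below `scotoma_radius` are "not seen" (threshold 0 dB); seen loci carry
#' positive thresholds decreasing with eccentricity plus noise.
#'
#' @param scotoma_radius central scotoma radius in degrees.
#' @param grid_loci number of grid loci (default 65).
#' @param ring_radii ring eccentricities in degrees.
#' @param seed RNG seed.
#' @param eye eye label.
#' @return A [sensitivity_map()].
#' @export
gen_sensitivity_map <- function(scotoma_radius = 0, grid_loci = 65,
                                ring_radii = c(2, 6, 10, 14, 18),
                                seed = NULL, eye = c("left", "right")) {
  check_number(scotoma_radius, "scotoma_radius", lower = 0)
  check_number(grid_loci, "grid_loci", lower = 1)
  g <- grid_layout(grid_loci, ring_radii)
  ecc <- sqrt(g$x_deg^2 + g$y_deg^2)
  noise <- with_seed(seed, stats::rnorm(nrow(g), 0, 1))
  thr <- pmin(36, pmax(0, 30 - 0.8 * ecc + noise))
  seen <- ecc >= scotoma_radius
  thr[!seen] <- 0
  sensitivity_map(data.frame(x_deg = g$x_deg, y_deg = g$y_deg,
                             threshold_db = thr, seen = seen),
                  eye = match.arg(eye))
}

# baseline metric profiles over eccentricity (degrees)
thickness_baseline <- function(ecc) 0.90 + 0.30 * exp(-ecc / 18)
ficvf_baseline <- function(ecc) 0.38 + 0.10 * (1 - exp(-ecc / 25))
odi_baseline <- function(ecc) 0.50 - 0.12 * (1 - exp(-ecc / 25))
REF_THICKNESS_MM <- 2.1

#' Attach synthetic per-vertex metric maps for one participant
#'
#' Thickness (mm), FICVF and ODI per vertex: an eccentricity-dependent
#' baseline (central cortex thicker, mirroring the V1 thickness gradient)
#' plus the cohort's diagnosis/interaction deflections, a participant-level
#' regional offset, and i.i.d. Gaussian vertex noise. Thickness deflections
#' are applied to V1 vertices with an exact per-hemisphere compensation on
#' non-V1 vertices so the hemispheric mean is untouched -- emulating that V1
#' occupies a tiny fraction of a real hemisphere, which keeps
#' hemispheric-mean normalization from cancelling V1 effects.
#'
#' @param surface a `retino_surface` without metrics.
#' @param cohort a [cohort_spec()].
#' @param diagnosis `"MD"` or `"HC"`.
#' @param onset `"early"` or `"late"`.
#' @param seed RNG seed for this participant's noise.
#' @param metrics which metric maps to generate (subset of
#'   `"thickness"`, `"ficvf"`, `"odi"`; default all three).
#' @return The surface with `thickness_mm`, `ficvf`, `odi` vertex columns.
#' @export
gen_metric_maps <- function(surface, cohort, diagnosis = c("MD", "HC"),
                            onset = c("early", "late"), seed = NULL,
                            metrics = c("thickness", "ficvf", "odi")) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  stopifnot(inherits(surface, "retino_surface"),
            inherits(cohort, "cohort_spec"))
  diagnosis <- match.arg(diagnosis); onset <- match.arg(onset)
  v <- surface$vertices
  if (!is.null(v$thickness_mm))
    vf_stop("invalid_parameter", "surface already carries metric maps")
  s_d <- if (diagnosis == "MD") 1 else -1
  s_o <- if (onset == "early") 1 else -1
  # V1-localized deflection weights, mean-zero within each hemisphere
  w <- numeric(nrow(v))
  for (h in unique(v$hemi)) {
    sel <- v$hemi == h
    n1 <- sum(sel & v$v1_flag); n0 <- sum(sel & !v$v1_flag)
    w[sel & v$v1_flag] <- 1
    if (n0 > 0) w[sel & !v$v1_flag] <- -n1 / n0
  }
  one <- function(effect_d, effect_i, part_sd, noise_sd, rng) {
    delta <- (effect_d / 2) * s_d + (effect_i / 2) * s_d * s_o +
      rng$part * part_sd
    delta * w + rng$noise * noise_sd
  }
  rngs <- with_seed(seed, stats::setNames(lapply(metrics, function(i)
    list(part = stats::rnorm(1), noise = stats::rnorm(nrow(v)))), metrics))
  if ("thickness" %in% metrics)
    surface$vertices$thickness_mm <- REF_THICKNESS_MM *
      (thickness_baseline(v$ecc_deg) +
         one(cohort$effect_diagnosis, cohort$effect_onset_x_diagnosis,
             cohort$participant_sd, cohort$noise_sd, rngs$thickness))
  if ("ficvf" %in% metrics)
    surface$vertices$ficvf <- pmin(1, pmax(0, ficvf_baseline(v$ecc_deg) +
      one(cohort$effect_diagnosis_ficvf,
          cohort$effect_onset_x_diagnosis_ficvf,
          cohort$participant_sd_ficvf, cohort$noise_sd_ficvf, rngs$ficvf)))
  if ("odi" %in% metrics)
    surface$vertices$odi <- pmin(1, pmax(0, odi_baseline(v$ecc_deg) +
      one(cohort$effect_diagnosis_odi, cohort$effect_onset_x_diagnosis_odi,
          cohort$participant_sd_odi, cohort$noise_sd_odi, rngs$odi)))
  surface
}

#' Generate a full synthetic study bundle
#'
#' Produces one matched cohort: `n_per_cell` MD participants per onset cell,
#' each with a one-to-one matched control sharing the MD participant's onset
#' label, plus per-eye fixation clouds and sensitivity maps, a shared
#' retinotopic surface (the template on which all ROIs are defined, so a
#' control's cortical ROIs equal its matched MD participant's), per-vertex
#' metric maps, and the design table. Fully reproducible from
#' `cohort$seed`.
#'
#' @param cohort a [cohort_spec()].
#' @param surface_spec a [surface_spec()].
#' @return Object of class `study_bundle`: list with `design` (data frame),
#'   `surface` (shared geometry), and `participants` (named list carrying
#'   per-participant `fixations`, `sensitivity`, `prl_center`, `metrics`).
#' @export
gen_cohort <- function(cohort = cohort_spec(),
                       surface_spec = vf2cortex::surface_spec()) {
  stopifnot(inherits(cohort, "cohort_spec"),
            inherits(surface_spec, "surface_spec"))
  surface_spec$seed <- derive_seed(cohort$seed, "surface")
  surface <- gen_surface(surface_spec)
  onsets <- rep(c("early", "late"), each = cohort$n_per_cell)
  md_ids <- sprintf("MD-%s-%02d", onsets, seq_len(cohort$n_per_cell))
  hc_ids <- sub("^MD", "HC", md_ids)

  design <- with_seed(derive_seed(cohort$seed, "design"), {
    age_md <- ifelse(onsets == "early",
                     stats::rnorm(length(onsets), 47.8, 20.8),
                     stats::rnorm(length(onsets), 70.9, 11.4))
    age_md <- pmin(90, pmax(18, round(age_md)))
    age_hc <- pmin(90, pmax(18, round(age_md + stats::rnorm(length(onsets), 0, 3))))
    ac_md <- ifelse(onsets == "early",
                    stats::rnorm(length(onsets), 1.12, 0.21),
                    stats::rnorm(length(onsets), 0.73, 0.40))
    ac_md <- round(pmin(2, pmax(0.1, ac_md)), 2)
    ac_hc <- round(pmin(0.5, pmax(-0.3, stats::rnorm(length(onsets), 0, 0.1))), 2)
    data.frame(
      participant = c(md_ids, hc_ids),
      diagnosis = rep(c("MD", "HC"), each = length(md_ids)),
      onset = c(onsets, onsets),
      age = c(age_md, age_hc),
      acuity_logmar = c(ac_md, ac_hc),
      matched_id = c(hc_ids, md_ids))
  })

  # per-participant sub-seeds drawn from a master stream (robust against
  # seed-arithmetic correlations in the generator RNG)
  seed_tags <- c("prl", "fixL", "fixR", "senL", "senR", "met")
  seed_tab <- with_seed(derive_seed(cohort$seed, "participants"),
                        matrix(sample.int(2147483646L,
                                          nrow(design) * length(seed_tags)),
                               nrow(design), length(seed_tags),
                               dimnames = list(design$participant,
                                               seed_tags)))

  gen_participant <- function(id, diagnosis, onset) {
    sd_id <- function(tag) seed_tab[id, tag]
    md <- diagnosis == "MD"
    prl <- with_seed(sd_id("prl"), {
      ecc <- max(cohort$scotoma_radius_deg + 0.5,
                 stats::rnorm(1, cohort$prl_ecc_deg, cohort$prl_sd_deg))
      # keep the PRL within the sensitivity-grid extent (observed PRLs
      # reach ~20 deg) and inside the surface's field coverage
      ecc <- min(ecc, 19, surface_spec$max_ecc_deg - 5)
      ang <- stats::runif(1, -180, 180)
      c(ecc * cos(deg2rad(ang)), ecc * sin(deg2rad(ang)))
    })
    ctr <- if (md) prl else c(0, 0)
    sig <- if (md) cohort$fix_sigma_deg else cohort$hc_fix_sigma_deg
    scot <- if (md) cohort$scotoma_radius_deg else 0
    list(
      fixations = list(
        left = gen_fixations(ctr, sig, sig, 0, cohort$n_fixations,
                             seed = sd_id("fixL"), eye = "left"),
        right = gen_fixations(ctr + c(0.2, -0.1), sig, sig, 0,
                              cohort$n_fixations, seed = sd_id("fixR"),
                              eye = "right")),
      sensitivity = list(
        left = gen_sensitivity_map(scot, seed = sd_id("senL"), eye = "left"),
        right = gen_sensitivity_map(scot, seed = sd_id("senR"),
                                    eye = "right")),
      better_eye = "left",
      prl_center = if (md) prl else NULL,
      metrics = {
        s <- gen_metric_maps(surface, cohort, diagnosis, onset,
                             seed = sd_id("met"))
        s$vertices[, c("vertex_id", "thickness_mm", "ficvf", "odi")]
      })
  }

  participants <- stats::setNames(
    lapply(seq_len(nrow(design)), function(i)
      gen_participant(design$participant[i], design$diagnosis[i],
                      design$onset[i])),
    design$participant)
  structure(list(design = design, surface = surface,
                 participants = participants,
                 cohort = cohort, surface_spec = surface_spec),
            class = "study_bundle")
}

#' @export
print.study_bundle <- function(x, ...) {
  cat(sprintf("<study_bundle> %d participants (%d MD, %d HC), surface %d vertices\n",
              nrow(x$design), sum(x$design$diagnosis == "MD"),
              sum(x$design$diagnosis == "HC"), nrow(x$surface$vertices)))
  invisible(x)
}

#' Surface with one participant's metric maps attached
#'
#' @param bundle a `study_bundle`.
#' @param participant participant id from the design table.
#' @return A `retino_surface` carrying that participant's metrics.
#' @export
participant_surface <- function(bundle, participant) {
  stopifnot(inherits(bundle, "study_bundle"))
  p <- bundle$participants[[participant]]
  if (is.null(p))
    vf_stop("invalid_parameter", "unknown participant '%s'", participant)
  s <- bundle$surface
  m <- p$metrics[match(s$vertices$vertex_id, p$metrics$vertex_id), ]
  s$vertices$thickness_mm <- m$thickness_mm
  s$vertices$ficvf <- m$ficvf
  s$vertices$odi <- m$odi
  s
}
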