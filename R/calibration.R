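# Monte-Carlo operating characteristics of the inference battery on
# synthetic cohorts.

#' Type-I error / power of the PRL-URL mixed ANOVA by simulation
#'
#' Builds one synthetic cohort geometry (surface, per-participant cPRL/cURL
#' through the full ROI pipeline, with controls inheriting their matched MD
#' participant's ROIs), then repeatedly regenerates participant-level
#' metric noise, extracts ROI means of normalized thickness and runs the
#' mixed ANOVA, recording rejections at `alpha` per effect.
#'
#' Two design choices keep the experiment honest and affordable: the ROI
#' geometry is fixed across repetitions (it does not affect the error
#' calibration of the test, and regenerating meshes thousands of times
#' would dominate the runtime), and PRL placement uses a fixed eccentricity
#' (`prl_sd_deg = 0`, angles still random) so that participants are
#' exchangeable under the null -- with heterogeneous PRL eccentricities the
#' matched design shares ROI-position variance between the groups and the
#' unpaired ANOVA becomes conservative, which is a property of the design,
#' not of the test.
#'
#' `interaction_d` injects a diagnosis-by-onset interaction expressed in
#' units of the participant-level pooled SD of the dependent variable
#' (Cohen-style standardized deflection; see [cohort_spec()] for the
#' sum-to-zero convention).
#'
#' @param n_reps Monte-Carlo repetitions.
#' @param n_per_cell participants per diagnosis x onset cell.
#' @param interaction_d standardized interaction deflection (0 = null).
#' @param seed RNG seed.
#' @param surface_n vertices per hemisphere of the template surface.
#' @param alpha rejection level.
#' @return List: `rates` (named rejection proportions per effect),
#'   `n_reps`, `effect_sd` (the participant-level SD used to scale
#'   `interaction_d`).
#' @export
simulate_rejection_rates <- function(n_reps = 1000, n_per_cell = 8,
                                     interaction_d = 0, seed = 1,
                                     surface_n = 2000, alpha = 0.05) {
  check_number(n_reps, "n_reps", lower = 1)
  base <- cohort_spec(n_per_cell = n_per_cell, effect_diagnosis = 0,
                      effect_onset_x_diagnosis = 0, prl_sd_deg = 0,
                      seed = derive_seed(seed, "geometry"))
  bundle <- gen_cohort(base, surface_spec(surface_n,
                                          seed = derive_seed(seed, "surf")))
  rois <- run_pipeline(bundle, pipeline_config())$rois
  surf <- bundle$surface
  design <- bundle$design
  idx <- lapply(design$participant, function(id)
    lapply(rois[[id]][c("cPRL", "cURL")], function(r)
      match(roi_vertex_ids(r), surf$vertices$vertex_id)))
  v_mean <- mean(vapply(idx, function(ii)
    mean(lengths(ii)), numeric(1)))
  effect_sd <- sqrt(base$participant_sd^2 + base$noise_sd^2 / v_mean)
  spec <- base
  spec$effect_onset_x_diagnosis <- interaction_d * effect_sd

  n <- nrow(design)
  template <- data.frame(
    participant = rep(design$participant, 2),
    diagnosis = rep(design$diagnosis, 2),
    onset = rep(design$onset, 2),
    roi_label = rep(c("cPRL", "cURL"), each = n))
  rates <- NULL
  # participant seeds drawn from a master stream: arithmetic seed patterns
  # (constant differences between paired participants) leak correlation
  # through Mersenne-Twister initialization
  seed_tab <- with_seed(derive_seed(seed, "mc"),
                        matrix(sample.int(2147483646L, n_reps * n),
                               n_reps, n))
  for (r in seq_len(n_reps)) {
    vals <- vapply(seq_len(n), function(i) {
      s <- gen_metric_maps(surf, spec, design$diagnosis[i], design$onset[i],
                           seed = seed_tab[r, i],
                           metrics = "thickness")
      s <- normalize_thickness(s)
      ii <- idx[[i]]
      c(mean(s$vertices$thickness_norm[ii$cPRL]),
        mean(s$vertices$thickness_norm[ii$cURL]))
    }, numeric(2))
    template$value <- c(vals[1, ], vals[2, ])
    a <- mixed_anova(template, "value", within = "roi_label",
                     between = c("diagnosis", "onset"))
    rej <- as.integer(a$effects$p < alpha)
    if (is.null(rates)) {
      rates <- rej
      names(rates) <- a$effects$effect
    } else rates <- rates + rej
  }
  list(rates = rates / n_reps, n_reps = n_reps, effect_sd = effect_sd,
       roi_vertices = v_mean)
}
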