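# End-to-end orchestration: microperimetry -> visual-field ROIs -> cortical
# ROIs -> metric table -> inference battery.

#' Pipeline configuration
#'
#' @param bcea_threshold_deg PRL eccentricity above which the 95% BCEA is
#'   used instead of the 63% one (default 7).
#' @param raster_step_deg ROI raster step in degrees (default 0.1).
#' @param min_vertices minimum cortical ROI size after dilation (default 50).
#' @param lpz_per_hemi LPZ vertices per hemisphere (default 100).
#' @param band_mode `"fixed"` (conventional eight-band limits) or
#'   `"quantile"` (equal vertex counts).
#' @param n_bands number of eccentricity bands (default 8).
#' @param url_candidates angular resolution of URL placement (default 72).
#' @param sphericity_alpha alpha for the conditional Huynh-Feldt correction.
#' @param q_fdr FDR level for post-hoc tests.
#' @param seed seed recorded in the provenance record.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(bcea_threshold_deg = 7, raster_step_deg = 0.1,
                            min_vertices = 50, lpz_per_hemi = 100,
                            band_mode = c("fixed", "quantile"), n_bands = 8,
                            url_candidates = 72, sphericity_alpha = 0.05,
                            q_fdr = 0.05, seed = NULL) {
  band_mode <- match.arg(band_mode)
  check_number(bcea_threshold_deg, "bcea_threshold_deg", lower = 0)
  check_number(raster_step_deg, "raster_step_deg", lower = 0,
               strict_lower = TRUE)
  check_number(min_vertices, "min_vertices", lower = 1)
  check_number(lpz_per_hemi, "lpz_per_hemi", lower = 1)
  structure(list(bcea_threshold_deg = bcea_threshold_deg,
                 raster_step_deg = raster_step_deg,
                 min_vertices = min_vertices, lpz_per_hemi = lpz_per_hemi,
                 band_mode = band_mode, n_bands = as.integer(n_bands),
                 url_candidates = url_candidates,
                 sphericity_alpha = sphericity_alpha, q_fdr = q_fdr,
                 seed = seed),
            class = "pipeline_config")
}

#' Define the PRL and URL for one participant's microperimetry
#'
#' Fixation cloud of the better eye -> PRL center and eccentricity ->
#' coverage level -> BCEA ellipse raster -> trim to binocular seeing retina
#' -> URL placement.
#'
#' @param fix_better better-eye [fixation_cloud()].
#' @param sens_left,sens_right per-eye [sensitivity_map()]s.
#' @param config a [pipeline_config()].
#' @return List: `prl`, `url` (vf_roi), `fused` map, `bcea`, `summary`.
#' @export
define_retinal_rois <- function(fix_better, sens_left, sens_right,
                                config = pipeline_config()) {
  ctr <- compute_prl_center(fix_better)
  ecc <- roi_eccentricity(ctr)
  coverage <- select_bcea_level(ecc, config$bcea_threshold_deg)
  bcea <- fit_bcea(fix_better, coverage)
  fused <- overlay_eyes(sens_left, sens_right)
  prl <- rasterize_bcea(bcea, step = config$raster_step_deg, role = "PRL")
  prl <- trim_to_seeing(prl, fused)
  url <- place_url(prl, fused, n_candidates = config$url_candidates)
  list(prl = prl, url = url, fused = fused, bcea = bcea,
       summary = list(center = unname(ctr), sigma_h = bcea$sigma_h,
                      sigma_v = bcea$sigma_v, rho = bcea$rho,
                      coverage = coverage, area_deg2 = roi_area(prl),
                      eccentricity_deg = ecc,
                      url_transform = url$meta$url_transform,
                      url_ties = url$meta$url_ties))
}

#' Run the full analysis pipeline on a study bundle
#'
#' For every MD participant: retinal ROI definition, projection to the
#' cortical surface, dilation to the minimum vertex count, with the matched
#' control inheriting the MD participant's cortical ROIs. The lesion
#' projection zone and eccentricity bands are defined on the shared
#' template. Thickness is hemisphere-normalized, per-ROI metric means are
#' extracted, and the inference battery is run (mixed ANOVA and ANCOVA at
#' the PRL/URL, a between-only ANOVA at the LPZ, an eccentricity-band mixed
#' ANOVA with Huynh-Feldt handling, and FDR-corrected per-band post-hocs),
#' for each of normalized thickness, FICVF and ODI. A failing participant
#' aborts the run with an identifying error; nothing is silently dropped.
#'
#' @param bundle a `study_bundle` (from [gen_cohort()] or [read_cohort()]).
#' @param config a [pipeline_config()].
#' @return List: `metric_table`, `design`, `rois`, `roi_summaries`,
#'   `effects` (named `anova_result`s), `posthoc` (per metric), and
#'   `provenance`.
#' @export
run_pipeline <- function(bundle, config = pipeline_config()) {
  stopifnot(inherits(bundle, "study_bundle"),
            inherits(config, "pipeline_config"))
  design <- bundle$design
  surface <- bundle$surface
  lpz <- define_lpz(surface, config$lpz_per_hemi)
  bands <- define_eccentricity_bands(
    surface, config$n_bands,
    fixed_ranges = if (config$band_mode == "fixed") {
      lim <- eccentricity_band_limits()
      mx <- max(surface$vertices$ecc_deg[surface$vertices$v1_flag])
      lim[length(lim)] <- max(lim[length(lim)], mx)
      lim
    })

  md_ids <- design$participant[design$diagnosis == "MD"]
  rois <- list(); roi_summaries <- list()
  for (id in md_ids) {
    p <- bundle$participants[[id]]
    res <- tryCatch(
      define_retinal_rois(p$fixations[[p$better_eye]],
                          p$sensitivity$left, p$sensitivity$right, config),
      error = function(e)
        vf_stop("participant_error", "participant %s: %s", id,
                conditionMessage(e)))
    cprl <- dilate_roi(map_roi_to_surface(res$prl, surface), surface,
                       config$min_vertices)
    curl <- dilate_roi(map_roi_to_surface(res$url, surface), surface,
                       config$min_vertices)
    rois[[id]] <- list(cPRL = cprl, cURL = curl, LPZ = lpz)
    roi_summaries[[id]] <- res$summary
  }
  # matched controls inherit the MD participant's cortical ROI definitions
  for (i in which(design$diagnosis == "HC")) {
    id <- design$participant[i]
    m <- design$matched_id[i]
    if (!m %in% names(rois))
      vf_stop("participant_error",
              "control %s: matched MD participant %s not found", id, m)
    rois[[id]] <- rois[[m]]
  }

  mt <- do.call(rbind, lapply(design$participant, function(id) {
    s <- normalize_thickness(participant_surface(bundle, id))
    extract_roi_metrics(s, c(rois[[id]], bands), participant = id)
  }))
  tab <- merge(mt, design, by = "participant")

  # participant-level ANCOVA covariates: mean PRL/URL ROI size and
  # eccentricity (log then centered); shared with the matched control by
  # construction (identical ROI definitions on the shared template)
  pu <- tab[tab$roi_label %in% c("cPRL", "cURL") &
              tab$metric == "thickness_norm", ]
  cov_df <- stats::aggregate(cbind(roi_size = n_vertices,
                                   roi_ecc = mean_ecc) ~ participant,
                             pu, mean)
  cov_df <- prepare_covariates(cov_df, ecc = "roi_ecc", size = "roi_size")
  tab <- merge(tab, cov_df, by = "participant")

  effects <- list(); posthoc <- list()
  for (metric in c("thickness_norm", "ficvf", "odi")) {
    sub <- tab[tab$metric == metric, ]
    pu <- sub[sub$roi_label %in% c("cPRL", "cURL"), ]
    lp <- sub[sub$roi_label == "LPZ", ]
    bnd <- sub[grepl("^ecc-band-", sub$roi_label), ]
    effects[[paste0(metric, "_prl_url")]] <-
      mixed_anova(pu, "value", within = "roi_label",
                  between = c("diagnosis", "onset"),
                  sphericity_alpha = config$sphericity_alpha)
    effects[[paste0(metric, "_prl_url_ancova")]] <-
      mixed_ancova(pu, "value", within = "roi_label",
                   between = c("diagnosis", "onset"),
                   covariates = c("roi_ecc_logc", "roi_size_c"),
                   sphericity_alpha = config$sphericity_alpha)
    effects[[paste0(metric, "_lpz")]] <-
      mixed_anova(lp, "value", within = NULL,
                  between = c("diagnosis", "onset"))
    effects[[paste0(metric, "_bands")]] <-
      mixed_anova(bnd, "value", within = "roi_label",
                  between = c("diagnosis", "onset"),
                  sphericity_alpha = config$sphericity_alpha)
    posthoc[[metric]] <- posthoc_fdr(bnd, "value", "diagnosis",
                                     q = config$q_fdr)
  }

  provenance <- list(
    config = unclass(config),
    n_participants = nrow(design),
    roi_log = lapply(rois[md_ids], function(r)
      list(cPRL_rings = r$cPRL$meta$dilation_rings,
           cPRL_n = r$cPRL$n_vertices,
           cURL_rings = r$cURL$meta$dilation_rings,
           cURL_n = r$cURL$n_vertices)),
    url_log = lapply(roi_summaries, function(s)
      list(transform = s$url_transform, ties = s$url_ties)),
    band_mode = config$band_mode,
    ss_type = "III")

  list(metric_table = mt, design = design, rois = rois,
       roi_summaries = roi_summaries, effects = effects, posthoc = posthoc,
       provenance = provenance)
}

#' Write pipeline results to a directory
#'
#' `metric_table.csv`, per-analysis effect tables under `effects_*.csv`,
#' `roi_labels.csv` (participant, vertex_id, hemi, label) and
#' `provenance.json`.
#'
#' @param result a [run_pipeline()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_results <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$metric_table, file.path(dir, "metric_table.csv"),
                   row.names = FALSE)
  for (nm in names(result$effects)) {
    e <- result$effects[[nm]]
    df <- e$effects
    df$mauchly_W <- e$mauchly_W; df$mauchly_p <- e$mauchly_p
    df$epsilon_hf <- e$epsilon_hf
    utils::write.csv(df, file.path(dir, paste0("effects_", nm, ".csv")),
                     row.names = FALSE)
  }
  labels <- do.call(rbind, lapply(names(result$rois), function(id) {
    do.call(rbind, lapply(names(result$rois[[id]]), function(lab) {
      r <- result$rois[[id]][[lab]]
      data.frame(participant = id,
                 vertex_id = roi_vertex_ids(r),
                 hemi = rep(c("lh", "rh"),
                            c(length(r$vertices$lh), length(r$vertices$rh))),
                 label = lab)
    }))
  }))
  utils::write.csv(labels, file.path(dir, "roi_labels.csv"),
                   row.names = FALSE)
  jsonlite::write_json(result$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
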