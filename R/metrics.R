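# Thickness normalization and per-ROI metric aggregation.

#' Normalize cortical thickness to the hemispheric mean
#'
#' Adds a `thickness_norm` column: each vertex's thickness divided by the
#' mean thickness over all valid vertices of its hemisphere (not only V1).
#' By construction the per-hemisphere mean of `thickness_norm` over valid
#' vertices is exactly 1, and the result is invariant to rescaling the raw
#' thicknesses.
#'
#' @param surface a `retino_surface` carrying `thickness_mm`.
#' @return The surface with a `thickness_norm` vertex column.
#' @export
normalize_thickness <- function(surface) {
  stopifnot(inherits(surface, "retino_surface"))
  v <- surface$vertices
  if (is.null(v$thickness_mm))
    vf_stop("missing_annotation", "surface has no thickness_mm metric")
  ok <- valid_vertices(surface)
  out <- rep(NA_real_, nrow(v))
  for (h in unique(v$hemi)) {
    sel <- v$hemi == h & ok
    m <- mean(v$thickness_mm[sel])
    if (!length(which(sel)) || !is.finite(m) || m <= 0)
      vf_stop("normalization_error",
              "hemisphere %s mean thickness undefined or non-positive", h)
    out[v$hemi == h] <- v$thickness_mm[v$hemi == h] / m
  }
  surface$vertices$thickness_norm <- out
  surface
}

#' Extract per-ROI metric means into a tidy table
#'
#' Unweighted means over each ROI's valid vertices, pooling hemispheres for
#' split ROIs. Vertices failing the validity mask are omitted from both the
#' numerator and the count.
#'
#' @param surface a `retino_surface` with metric columns.
#' @param rois list of `cortical_roi` objects (a single ROI is accepted).
#' @param metrics character vector of vertex metric columns (default all of
#'   `thickness_norm`, `thickness_mm`, `ficvf`, `odi` that are present).
#' @param participant optional participant id recorded in the table.
#' @return Data frame with columns `participant`, `roi_label`, `metric`,
#'   `value`, `n_vertices`, `mean_ecc` (class `metric_table`).
#' @export
extract_roi_metrics <- function(surface, rois, metrics = NULL,
                                participant = NA_character_) {
  stopifnot(inherits(surface, "retino_surface"))
  if (inherits(rois, "cortical_roi")) rois <- list(rois)
  if (!length(rois)) vf_stop("invalid_parameter", "no ROIs supplied")
  v <- surface$vertices
  if (is.null(metrics))
    metrics <- intersect(c("thickness_norm", "thickness_mm", "ficvf", "odi"),
                         names(v))
  missing <- setdiff(metrics, names(v))
  if (length(missing))
    vf_stop("missing_annotation", "surface lacks metric(s): %s",
            paste(missing, collapse = ", "))
  ok <- valid_vertices(surface)
  rows <- lapply(rois, function(r) {
    idx <- match(roi_vertex_ids(r), v$vertex_id)
    idx <- idx[ok[idx]]
    if (!length(idx))
      vf_stop("empty_aggregate", "ROI %s has no valid vertices", r$label)
    data.frame(participant = participant, roi_label = r$label,
               metric = metrics,
               value = vapply(metrics, function(m) mean(v[[m]][idx]),
                              numeric(1)),
               n_vertices = length(idx),
               mean_ecc = mean(v$ecc_deg[idx]), row.names = NULL)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("metric_table", "data.frame")
  out
}
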