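# Projection of visual-field ROIs onto V1 surface vertices: nearest-cell
# matching, one-ring dilation with non-V1 pruning, LPZ and eccentricity
# bands.

new_cortical_roi <- function(label, lh, rh, surface, meta = list()) {
  ids <- c(lh, rh)
  ecc <- surface$vertices$ecc_deg[match(ids, surface$vertices$vertex_id)]
  structure(list(label = label,
                 vertices = list(lh = sort(lh), rh = sort(rh)),
                 n_vertices = length(ids),
                 mean_ecc = if (length(ids)) mean(ecc) else NA_real_,
                 meta = meta),
            class = "cortical_roi")
}

#' All vertex ids of a cortical ROI
#' @param roi a `cortical_roi`.
#' @export
roi_vertex_ids <- function(roi) c(roi$vertices$lh, roi$vertices$rh)

#' @export
print.cortical_roi <- function(x, ...) {
  cat(sprintf("<cortical_roi> %s: %d vertices (lh %d, rh %d), mean ecc %.2f deg\n",
              x$label, x$n_vertices, length(x$vertices$lh),
              length(x$vertices$rh), x$mean_ecc))
  invisible(x)
}

#' Hemisphere receiving a visual-field point
#'
#' Contralateral convention: the left visual hemifield (x < 0) projects to
#' the right hemisphere and vice versa; points on the vertical meridian
#' (x = 0) belong to both (vertex matching resolves the assignment).
#'
#' @param point length-2 numeric `(x, y)` in field degrees.
#' @return `"lh"`, `"rh"`, or `c("lh", "rh")` on the meridian.
#' @export
field_to_hemifield <- function(point) {
  if (length(point) != 2L || !all(is.finite(point)))
    vf_stop("invalid_parameter", "point must be finite (x, y)")
  if (point[1] > 0) "lh" else if (point[1] < 0) "rh" else c("lh", "rh")
}

#' Project a visual-field ROI onto V1 surface vertices
#'
#' For every V1 vertex, its retinotopic coordinates are converted to field
#' Cartesian coordinates and the nearest ROI-raster cell center (Euclidean
#' distance over the full raster extent, ties to the lowest cell index) is
#' located; the vertex joins the cortical ROI iff that cell is inside the
#' ROI mask. Matching in field Cartesian space avoids the anisotropy of raw
#' (eccentricity, polar angle) distances near the fovea.
#'
#' @param roi a `vf_roi`.
#' @param surface a `retino_surface`.
#' @return A `cortical_roi` labelled `"c<role>"`.
#' @export
map_roi_to_surface <- function(roi, surface) {
  stopifnot(inherits(roi, "vf_roi"))
  if (!inherits(surface, "retino_surface") ||
      is.null(surface$vertices$ecc_deg) || is.null(surface$vertices$angle_deg))
    vf_stop("missing_annotation", "surface lacks retinotopic annotation")
  v <- surface$vertices
  sel <- v$v1_flag
  pts <- cbind(v$x_deg[sel], v$y_deg[sel])
  # canonical raster frame; nearest cell of a regular grid by clamped floor
  z <- pts %*% roi$R
  i <- pmin(roi$dim[1], pmax(1, floor((z[, 1] - roi$origin[1]) / roi$step) + 1))
  j <- pmin(roi$dim[2], pmax(1, floor((z[, 2] - roi$origin[2]) / roi$step) + 1))
  inside <- roi$mask[(j - 1) * roi$dim[1] + i]
  ids <- v$vertex_id[sel][inside]
  hemi <- v$hemi[sel][inside]
  new_cortical_roi(paste0("c", roi$role),
                   lh = ids[hemi == "lh"], rh = ids[hemi == "rh"], surface,
                   meta = list(source_role = roi$role,
                               raster_step = roi$step))
}

#' Dilate a cortical ROI to a minimum vertex count
#'
#' Iterative one-ring mesh dilation. If the ROI spans both hemispheres, only
#' the larger portion grows while the smaller portion stays fixed (ties go
#' to the left hemisphere, recorded in metadata). After each ring, vertices
#' outside V1 are pruned; dilation stops once the combined pruned count
#' reaches `min_vertices`.
#'
#' @param roi a `cortical_roi`.
#' @param surface a `retino_surface`.
#' @param min_vertices target size (default 50).
#' @return The dilated `cortical_roi`; metadata records rings used.
#' @export
dilate_roi <- function(roi, surface, min_vertices = 50) {
  stopifnot(inherits(roi, "cortical_roi"), inherits(surface, "retino_surface"))
  check_number(min_vertices, "min_vertices", lower = 1)
  if (roi$n_vertices == 0L) vf_stop("empty_roi", "cannot dilate an empty ROI")
  v <- surface$vertices
  v1_ids <- v$vertex_id[v$v1_flag]
  hemi_of <- function(ids) v$hemi[match(ids, v$vertex_id)]
  lh <- roi$vertices$lh; rh <- roi$vertices$rh
  grow_lh <- length(lh) >= length(rh)  # ties -> lh
  if (!length(lh)) grow_lh <- FALSE
  if (!length(rh)) grow_lh <- TRUE
  growing <- if (grow_lh) lh else rh
  fixed <- if (grow_lh) rh else lh
  rings <- 0L
  total <- function() length(growing) + length(fixed)
  while (total() < min_vertices) {
    nb <- unique(unlist(surface$adjacency[growing], use.names = FALSE))
    new_set <- unique(c(growing, nb))
    new_set <- new_set[new_set %in% v1_ids]  # prune non-V1 after each ring
    if (length(new_set) == length(growing))
      vf_stop("insufficient_surface",
              "mesh exhausted at %d vertices before reaching %d",
              total(), min_vertices)
    growing <- new_set
    rings <- rings + 1L
  }
  out_lh <- if (grow_lh) growing else fixed
  out_rh <- if (grow_lh) fixed else growing
  out <- new_cortical_roi(roi$label, out_lh, out_rh, surface,
                          meta = roi$meta)
  out$meta$dilation_rings <- rings
  out$meta$dilated_hemi <- if (rings > 0L) (if (grow_lh) "lh" else "rh") else NA
  out
}

#' Define the lesion projection zone (LPZ)
#'
#' The `n_per_hemi` V1 vertices with the lowest eccentricity on each
#' hemisphere (default 100, i.e. 200 vertices total). Ties at the cutoff are
#' broken by vertex id.
#'
#' @param surface a `retino_surface`.
#' @param n_per_hemi vertices per hemisphere (default 100).
#' @return A `cortical_roi` labelled `"LPZ"`.
#' @export
define_lpz <- function(surface, n_per_hemi = 100) {
  stopifnot(inherits(surface, "retino_surface"))
  check_number(n_per_hemi, "n_per_hemi", lower = 1)
  v <- surface$vertices[surface$vertices$v1_flag, ]
  pick <- function(h) {
    vh <- v[v$hemi == h, ]
    if (nrow(vh) < n_per_hemi)
      vf_stop("insufficient_surface",
              "hemisphere %s has %d V1 vertices, need %d", h, nrow(vh),
              n_per_hemi)
    vh$vertex_id[order(vh$ecc_deg, vh$vertex_id)][seq_len(n_per_hemi)]
  }
  new_cortical_roi("LPZ", pick("lh"), pick("rh"), surface,
                   meta = list(n_per_hemi = n_per_hemi))
}

#' Define eccentricity-band ROIs over V1
#'
#' Splits V1 into `n_bands` eccentricity bands per hemisphere with limits
#' shared across hemispheres. With `fixed_ranges` the supplied limits are
#' used (half-open intervals `[lo, hi)`, last interval closed); otherwise
#' limits are chosen at pooled-across-hemisphere vertex-count quantiles so
#' band sizes are equal to within one vertex.
#'
#' @param surface a `retino_surface`.
#' @param n_bands number of bands (default 8).
#' @param fixed_ranges optional numeric vector of `n_bands + 1` ordered
#'   limits. `eccentricity_band_limits()` returns the conventional
#'   eight-band set.
#' @return List of `cortical_roi` objects labelled `"ecc-band-<k>"`; each
#'   carries its `[lo, hi)` limits in metadata.
#' @export
define_eccentricity_bands <- function(surface, n_bands = 8,
                                      fixed_ranges = NULL) {
  stopifnot(inherits(surface, "retino_surface"))
  check_number(n_bands, "n_bands", lower = 2)
  n_bands <- as.integer(n_bands)
  v <- surface$vertices[surface$vertices$v1_flag, ]
  if (!is.null(fixed_ranges)) {
    if (length(fixed_ranges) != n_bands + 1L || is.unsorted(fixed_ranges))
      vf_stop("invalid_parameter",
              "fixed_ranges must be %d ordered limits", n_bands + 1L)
    lims <- as.numeric(fixed_ranges)
    if (min(v$ecc_deg) < lims[1] || max(v$ecc_deg) > lims[n_bands + 1L])
      vf_stop("uncovered_vertex",
              "eccentricity ranges do not cover all V1 vertices")
  } else {
    # midpoints between order statistics at equal-count chunk boundaries
    ecc <- sort(v$ecc_deg)
    n <- length(ecc)
    cut_idx <- floor(seq_len(n_bands - 1L) * n / n_bands)
    mids <- (ecc[cut_idx] + ecc[cut_idx + 1L]) / 2
    lims <- c(min(ecc), mids, max(ecc) + 1e-9)
  }
  band <- findInterval(v$ecc_deg, lims, rightmost.closed = TRUE,
                       left.open = FALSE)
  lapply(seq_len(n_bands), function(k) {
    ids <- v$vertex_id[band == k]
    hemi <- v$hemi[band == k]
    r <- new_cortical_roi(sprintf("ecc-band-%d", k),
                          lh = ids[hemi == "lh"], rh = ids[hemi == "rh"],
                          surface,
                          meta = list(lo = lims[k], hi = lims[k + 1L]))
    r
  })
}

#' Conventional eight-band eccentricity limits
#'
#' The fixed eccentricity limits (degrees) used for the eight-band V1
#' parcellation: 0, 2.0, 4.3, 6.8, 9.3, 15.7, 26.6, 45.4, 90.
#' @return Numeric vector of 9 limits.
#' @export
eccentricity_band_limits <- function() {
  c(0, 2.0, 4.3, 6.8, 9.3, 15.7, 26.6, 45.4, 90)
}
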