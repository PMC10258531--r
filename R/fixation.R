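#' Fixation cloud
#'
#' A per-eye set of fixation coordinates in visual-field degrees, relative to
#' the fovea. Raw microperimetry exports in image pixels are converted at
#' ingest: `(px - fovea_px) / px_per_deg`, with an optional 180-degree flip
#' for data recorded in retinal-image (inverted) space.
#'
#' @param points two-column matrix or data frame of (x, y) coordinates.
#' @param eye one of `"left"`, `"right"`.
#' @param fovea fovea coordinate in the same units as `points` (subtracted).
#' @param px_per_deg pixels-per-degree conversion; 1 when `points` are
#'   already in degrees.
#' @param flip if `TRUE`, apply a 180-degree flip (x, y -> -x, -y) to convert
#'   retinal-image coordinates to visual-field coordinates.
#' @return An object of class `fixation_cloud`: a list with `points` (n x 2
#'   matrix, degrees, fovea at origin), `eye`, `px_per_deg`.
#' @export
fixation_cloud <- function(points, eye = c("left", "right"),
                           fovea = c(0, 0), px_per_deg = 1, flip = FALSE) {
  eye <- match.arg(eye)
  pts <- as.matrix(points)
  if (ncol(pts) != 2L || !is.numeric(pts) || anyNA(pts))
    vf_stop("invalid_parameter", "fixation points must be a numeric n x 2 table")
  check_number(px_per_deg, "px_per_deg", lower = 0, strict_lower = TRUE)
  pts <- sweep(pts, 2L, as.numeric(fovea)) / px_per_deg
  if (flip) pts <- -pts
  dimnames(pts) <- list(NULL, c("x", "y"))
  structure(list(points = pts, eye = eye, px_per_deg = px_per_deg),
            class = "fixation_cloud")
}

#' @export
print.fixation_cloud <- function(x, ...) {
  ctr <- colMeans(x$points)
  cat(sprintf("<fixation_cloud> %s eye, %d points, mean (%.2f, %.2f) deg\n",
              x$eye, nrow(x$points), ctr[1], ctr[2]))
  invisible(x)
}

#' PRL center: mean of fixation locations
#'
#' The preferred retinal locus (PRL) center is the center of mass of the
#' fixation coordinates, in degrees relative to the fovea.
#'
#' @param cloud a [fixation_cloud()].
#' @return Numeric length-2 vector `(x, y)` in degrees.
#' @export
compute_prl_center <- function(cloud) {
  stopifnot(inherits(cloud, "fixation_cloud"))
  if (nrow(cloud$points) < 1L)
    vf_stop("empty_input", "fixation cloud has no points")
  colMeans(cloud$points)
}

#' Fit the bivariate contour ellipse area (BCEA)
#'
#' Fits a bivariate-normal model to a fixation cloud and returns the ellipse
#' expected to contain a fraction `coverage` of fixations:
#' `area = chi2q * pi * sigma_h * sigma_v * sqrt(1 - rho^2)` with
#' `chi2q = qchisq(coverage, df = 2) = -2 * log(1 - coverage)`.
#' Standard deviations use the n-1 (sample) denominator.
#'
#' @param cloud a [fixation_cloud()].
#' @param coverage ellipse probability content, in (0, 1); microperimeters
#'   conventionally report 0.63 and 0.95.
#' @return An object of class `bcea`: center, `sigma_h`, `sigma_v`, `rho`,
#'   `coverage`, `chi2_quantile`, `area_deg2`, and `ellipse` (semi-axes
#'   `a`, `b` and orientation `theta_deg` of the major axis).
#' @export
fit_bcea <- function(cloud, coverage = 0.63) {
  stopifnot(inherits(cloud, "fixation_cloud"))
  check_number(coverage, "coverage", lower = 0, upper = 1,
               strict_lower = TRUE)
  if (coverage >= 1)
    vf_stop("invalid_parameter", "coverage must be < 1")
  pts <- cloud$points
  if (nrow(pts) < 3L)
    vf_stop("invalid_parameter", "need at least 3 points for an ellipse fit")
  ctr <- colMeans(pts)
  S <- stats::cov(pts)
  sh <- sqrt(S[1, 1]); sv <- sqrt(S[2, 2])
  rho <- if (sh > 0 && sv > 0) S[1, 2] / (sh * sv) else 0
  q <- stats::qchisq(coverage, df = 2)
  det_ok <- det(S) > .Machine$double.eps * max(1, sum(diag(S)))^2
  area <- q * pi * sh * sv * sqrt(max(0, 1 - rho^2))
  ell <- NULL
  degenerate <- !det_ok
  if (det_ok) {
    e <- eigen(S, symmetric = TRUE)
    ell <- list(a = sqrt(q * e$values[1]), b = sqrt(q * e$values[2]),
                theta_deg = rad2deg(atan2(e$vectors[2, 1], e$vectors[1, 1])))
  } else {
    area <- 0
    warning("degenerate (collinear) fixation cloud; zero-area BCEA",
            call. = FALSE)
  }
  structure(list(center = ctr, sigma_h = sh, sigma_v = sv, rho = rho,
                 coverage = coverage, chi2_quantile = q, area_deg2 = area,
                 ellipse = ell, degenerate = degenerate, n = nrow(pts)),
            class = "bcea")
}

#' @export
print.bcea <- function(x, ...) {
  cat(sprintf(
    "<bcea> %d%% ellipse: center (%.2f, %.2f) deg, area %.2f deg^2 (sH %.2f, sV %.2f, rho %.2f)\n",
    round(100 * x$coverage), x$center[1], x$center[2], x$area_deg2,
    x$sigma_h, x$sigma_v, x$rho))
  invisible(x)
}

#' Choose the BCEA coverage level from PRL eccentricity
#'
#' The 95% ellipse is used for PRLs further from the fovea (to enlarge the
#' cortical ROI under cortical magnification), the 63% ellipse otherwise.
#' Ties at the threshold take the 63% level.
#'
#' @param prl_ecc PRL eccentricity in degrees.
#' @param threshold eccentricity cut, degrees (default 7).
#' @return 0.63 or 0.95.
#' @export
select_bcea_level <- function(prl_ecc, threshold = 7) {
  check_number(prl_ecc, "prl_ecc", lower = 0)
  check_number(threshold, "threshold", lower = 0)
  if (prl_ecc > threshold) 0.95 else 0.63
}

# ---- sensitivity maps -------------------------------------------------------

#' Sensitivity map
#'
#' A microperimetry grid: test loci with detection thresholds (dB) and a
#' seen/not-seen flag, in degrees relative to the fovea.
#'
#' @param loci data frame with columns `x_deg`, `y_deg`, `threshold_db`,
#'   `seen` (logical).
#' @param eye `"left"`, `"right"` or `"fused"`.
#' @param fovea fovea coordinate subtracted at ingest (same units as loci).
#' @return Object of class `sensitivity_map` (a data frame with attributes).
#' @export
sensitivity_map <- function(loci, eye = c("left", "right", "fused"),
                            fovea = c(0, 0)) {
  eye <- match.arg(eye)
  req <- c("x_deg", "y_deg", "threshold_db", "seen")
  if (!all(req %in% names(loci)))
    vf_stop("invalid_parameter", "sensitivity loci need columns %s",
            paste(req, collapse = ", "))
  loci <- as.data.frame(loci)[req]
  if (anyNA(loci$x_deg) || anyNA(loci$y_deg) ||
      !all(is.finite(loci$x_deg)) || !all(is.finite(loci$y_deg)))
    vf_stop("invalid_parameter", "locus coordinates must be finite")
  if (is.null(fovea) || length(fovea) != 2L || anyNA(fovea))
    vf_stop("alignment_error", "sensitivity map needs a fovea reference")
  loci$x_deg <- loci$x_deg - fovea[1]
  loci$y_deg <- loci$y_deg - fovea[2]
  loci$seen <- as.logical(loci$seen)
  structure(loci, eye = eye, class = c("sensitivity_map", "data.frame"))
}

#' Fuse the two eyes' sensitivity maps
#'
#' Both maps are already fovea-centered at ingest; loci are paired by
#' nearest neighbor within `pair_tol` degrees. A fused locus is seen if it
#' was seen in at least one eye, and carries the maximum threshold across
#' paired eyes. Unpaired loci are kept as-is.
#'
#' @param left,right `sensitivity_map` objects.
#' @param pair_tol pairing radius in degrees (default 0.5).
#' @return A fused `sensitivity_map`.
#' @export
overlay_eyes <- function(left, right, pair_tol = 0.5) {
  stopifnot(inherits(left, "sensitivity_map"),
            inherits(right, "sensitivity_map"))
  L <- as.data.frame(left); R <- as.data.frame(right)
  used_r <- rep(FALSE, nrow(R))
  out <- L
  for (i in seq_len(nrow(L))) {
    d2 <- (R$x_deg - L$x_deg[i])^2 + (R$y_deg - L$y_deg[i])^2
    d2[used_r] <- Inf
    j <- which.min(d2)
    if (length(j) && d2[j] <= pair_tol^2) {
      used_r[j] <- TRUE
      out$seen[i] <- L$seen[i] || R$seen[j]
      out$threshold_db[i] <- max(L$threshold_db[i], R$threshold_db[j],
                                 na.rm = TRUE)
    }
  }
  out <- rbind(out, R[!used_r, , drop = FALSE])
  rownames(out) <- NULL
  structure(out, eye = "fused", class = c("sensitivity_map", "data.frame"))
}

# ---- visual-field ROIs ------------------------------------------------------

# A vf_roi is a rasterized planar region. The raster lives in a canonical
# frame (axis-aligned grid: origin = lower-left corner, cell centers at
# origin + (i - 0.5) * step); `R` is an orthogonal 2x2 matrix mapping
# canonical coordinates to field coordinates (rotation/reflection about the
# fovea). URL candidates reuse the PRL raster with a different R, so the
# trimmed shape is inherited exactly.
new_vf_roi <- function(role, origin, step, dim, mask, R = diag(2),
                       center = NULL, meta = list()) {
  stopifnot(length(dim) == 2L, length(mask) == prod(dim))
  if (is.null(center)) {
    cc <- cell_centers(origin, step, dim)[mask, , drop = FALSE]
    center <- colMeans(cc)
  }
  structure(list(role = role, origin = origin, step = step, dim = dim,
                 mask = mask, R = R, center = center, meta = meta),
            class = "vf_roi")
}

cell_centers <- function(origin, step, dim) {
  ix <- rep(seq_len(dim[1]), times = dim[2])
  iy <- rep(seq_len(dim[2]), each = dim[1])
  cbind(x = origin[1] + (ix - 0.5) * step,
        y = origin[2] + (iy - 0.5) * step)
}

#' Active cell centers of a visual-field ROI, in field coordinates
#' @param roi a `vf_roi`.
#' @return n x 2 matrix of cell centers (degrees).
#' @export
roi_cells <- function(roi) {
  stopifnot(inherits(roi, "vf_roi"))
  cc <- cell_centers(roi$origin, roi$step, roi$dim)[roi$mask, , drop = FALSE]
  cc %*% t(roi$R)
}

#' ROI area in squared degrees
#' @param roi a `vf_roi`.
#' @export
roi_area <- function(roi) sum(roi$mask) * roi$step^2

#' ROI center in field coordinates
#' @param roi a `vf_roi`.
#' @export
roi_center <- function(roi) as.numeric(roi$R %*% roi$center)

#' @export
print.vf_roi <- function(x, ...) {
  ctr <- roi_center(x)
  cat(sprintf("<vf_roi> %s: %d cells @ %.2g deg, area %.2f deg^2, center (%.2f, %.2f), ecc %.2f deg\n",
              x$role, sum(x$mask), x$step, roi_area(x), ctr[1], ctr[2],
              roi_eccentricity(x)))
  invisible(x)
}

#' Rasterize a BCEA ellipse into a visual-field ROI
#'
#' Cells whose centers satisfy the ellipse quadratic form
#' `(z - mu)' S^-1 (z - mu) <= chi2_quantile` are marked active.
#'
#' @param bcea a [fit_bcea()] result.
#' @param step raster step in degrees (default 0.1).
#' @param role ROI label.
#' @return A `vf_roi`.
#' @export
rasterize_bcea <- function(bcea, step = 0.1, role = "PRL") {
  stopifnot(inherits(bcea, "bcea"))
  if (bcea$degenerate)
    vf_stop("degenerate_fit", "cannot rasterize a degenerate BCEA")
  check_number(step, "step", lower = 0, strict_lower = TRUE)
  S <- matrix(c(bcea$sigma_h^2,
                bcea$rho * bcea$sigma_h * bcea$sigma_v,
                bcea$rho * bcea$sigma_h * bcea$sigma_v,
                bcea$sigma_v^2), 2, 2)
  r <- sqrt(bcea$chi2_quantile * max(eigen(S, symmetric = TRUE)$values))
  lo <- bcea$center - r - step
  hi <- bcea$center + r + step
  dim <- pmax(1L, as.integer(ceiling((hi - lo) / step)))
  origin <- bcea$center - dim * step / 2
  cc <- cell_centers(origin, step, dim)
  d <- sweep(cc, 2L, bcea$center)
  Sinv <- solve(S)
  q <- rowSums((d %*% Sinv) * d)
  new_vf_roi(role, origin, step, dim, mask = q <= bcea$chi2_quantile,
             center = bcea$center,
             meta = list(coverage = bcea$coverage))
}

#' ROI eccentricity
#'
#' Euclidean distance from the fovea to the ROI center. When `px` distances
#' are supplied the `px_per_deg` factor converts them to degrees.
#'
#' @param roi a `vf_roi`, or a length-2 numeric center.
#' @param fovea fovea coordinate (default origin).
#' @param px_per_deg conversion factor when the center is in pixels.
#' @return Eccentricity in degrees.
#' @export
roi_eccentricity <- function(roi, fovea = c(0, 0), px_per_deg = 1) {
  ctr <- if (inherits(roi, "vf_roi")) roi_center(roi) else as.numeric(roi)
  check_number(px_per_deg, "px_per_deg", lower = 0, strict_lower = TRUE)
  sqrt(sum((ctr - as.numeric(fovea))^2)) / px_per_deg
}

# nearest-locus index for a set of points (rows) against a sensitivity map
nearest_locus <- function(pts, map) {
  m <- as.data.frame(map)
  apply(pts, 1L, function(p)
    which.min((m$x_deg - p[1])^2 + (m$y_deg - p[2])^2))
}

#' Trim an ROI to the seeing retina
#'
#' Removes raster cells whose nearest fused-map locus is not seen in either
#' eye (a bilateral scotoma). Idempotent; the role label is retained.
#'
#' @param roi a `vf_roi`.
#' @param fused a fused [sensitivity_map()].
#' @return The trimmed `vf_roi`.
#' @export
trim_to_seeing <- function(roi, fused) {
  stopifnot(inherits(roi, "vf_roi"), inherits(fused, "sensitivity_map"))
  idx <- which(roi$mask)
  if (!length(idx)) vf_stop("empty_roi", "ROI has no cells")
  pts <- roi_cells(roi)
  keep <- as.data.frame(fused)$seen[nearest_locus(pts, fused)]
  if (!any(keep))
    vf_stop("empty_roi",
            "ROI lies entirely within the bilateral scotoma after trimming")
  roi$mask[idx[!keep]] <- FALSE
  roi$meta$trimmed <- TRUE
  roi
}

#' Place the unpreferred retinal locus (URL)
#'
#' Duplicates the PRL shape and places it at equal eccentricity by either
#' reflecting across the vertical meridian, reflecting across the horizontal
#' meridian, or rotating about the fovea at `360 / n_candidates` degree
#' steps. The candidate containing the most seen fused loci wins; ties are
#' broken by the sum of thresholds at those loci, then by candidate order
#' (vertical flip, horizontal flip, smallest rotation angle). A trimmed PRL
#' propagates its trimmed shape to the URL unchanged.
#'
#' @param prl the PRL `vf_roi`.
#' @param fused fused [sensitivity_map()].
#' @param n_candidates angular resolution of the rotation set (default 72,
#'   i.e. 5-degree steps; the identity rotation is excluded).
#' @return A `vf_roi` with role `"URL"`; metadata records the winning
#'   transform and any score ties.
#' @export
place_url <- function(prl, fused, n_candidates = 72) {
  stopifnot(inherits(prl, "vf_roi"), inherits(fused, "sensitivity_map"))
  if (!sum(prl$mask)) vf_stop("empty_roi", "PRL is empty")
  check_number(n_candidates, "n_candidates", lower = 4)
  angles <- (seq_len(n_candidates - 1L)) * (360 / n_candidates)
  cands <- c(list(vflip = diag(c(-1, 1)) %*% prl$R,
                  hflip = diag(c(1, -1)) %*% prl$R),
             stats::setNames(lapply(angles, function(a) rot2(a) %*% prl$R),
                             sprintf("rot%.4g", angles)))
  m <- as.data.frame(fused)
  loci <- cbind(m$x_deg, m$y_deg)
  score <- function(R) {
    # pull loci into the canonical raster frame and test cell membership
    z <- loci %*% R    # == t(t(R) %*% t(loci)); R orthogonal so R^-1 = R'
    i <- floor((z[, 1] - prl$origin[1]) / prl$step) + 1
    j <- floor((z[, 2] - prl$origin[2]) / prl$step) + 1
    ok <- i >= 1 & i <= prl$dim[1] & j >= 1 & j <= prl$dim[2]
    inside <- ok
    inside[ok] <- prl$mask[(j[ok] - 1) * prl$dim[1] + i[ok]]
    hit <- inside & m$seen
    c(n = sum(hit), db = sum(m$threshold_db[hit]))
  }
  sc <- vapply(cands, score, numeric(2))
  if (max(sc["n", ]) == 0)
    vf_stop("no_valid_url", "no URL candidate contains a seen locus")
  best_n <- sc["n", ] == max(sc["n", ])
  best_db <- sc["db", ] == max(sc["db", best_n])
  winner <- which(best_n & best_db)[1L]
  url <- prl
  url$role <- "URL"
  url$R <- cands[[winner]]
  url$meta$url_transform <- names(cands)[winner]
  url$meta$url_ties <- names(cands)[best_n & best_db]
  url
}
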