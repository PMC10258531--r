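#' Surface specification for the synthetic retinotopic mesh
#'
#' Parameters of the synthetic V1 sheet. Vertices are laid out with areal
#' density proportional to the squared cortical magnification
#' `M(e) = A / (e + e0)` so that the central field is over-represented, as
#' in real V1.
#'
#' @param n_vertices_per_hemi approximate V1 vertex count per hemisphere
#'   (>= 300). The realized count is `n_rings * n_spokes` and is reported in
#'   the surface metadata.
#' @param max_ecc_deg visual-field extent in degrees (default 90).
#' @param magnification_A_mm,magnification_e0_deg cortical-magnification
#'   parameters; defaults A = 17.3 mm, e0 = 0.75 deg (standard human V1
#'   values).
#' @param seed RNG seed for the sub-ring jitter.
#' @return An object of class `surface_spec`.
#' @export
surface_spec <- function(n_vertices_per_hemi = 2000, max_ecc_deg = 90,
                         magnification_A_mm = 17.3,
                         magnification_e0_deg = 0.75, seed = NULL) {
  check_number(n_vertices_per_hemi, "n_vertices_per_hemi", lower = 300)
  check_number(max_ecc_deg, "max_ecc_deg", lower = 0, strict_lower = TRUE)
  check_number(magnification_A_mm, "magnification_A_mm", lower = 0,
               strict_lower = TRUE)
  check_number(magnification_e0_deg, "magnification_e0_deg", lower = 0,
               strict_lower = TRUE)
  structure(list(n_vertices_per_hemi = as.integer(n_vertices_per_hemi),
                 max_ecc_deg = max_ecc_deg,
                 magnification_A_mm = magnification_A_mm,
                 magnification_e0_deg = magnification_e0_deg,
                 seed = seed),
            class = "surface_spec")
}

# CDF of the M(e)^2-weighted radial density p(e) ~ M(e)^2 * 2*pi*e:
# integral of e / (e + e0)^2 = log(e + e0) + e0 / (e + e0)
radial_cdf <- function(e, e0) {
  f <- function(x) log(x + e0) + e0 / (x + e0)
  f(e) - f(0)
}

# quantile function of the radial density on [0, emax], by monotone
# interpolation over a fine grid
radial_quantile <- function(p, e0, emax) {
  g <- seq(0, emax, length.out = 4096L)
  cdf <- radial_cdf(g, e0)
  cdf <- cdf / cdf[length(cdf)]
  stats::approx(cdf, g, xout = p, ties = "ordered")$y
}

#' Generate a synthetic retinotopically annotated V1 surface
#'
#' Builds one triangulated sheet per hemisphere. Vertices sit on `n_rings`
#' eccentricity rings placed at quantiles of the magnification-weighted
#' radial density (so annulus vertex counts follow the integral of
#' `M(e)^2 * 2*pi*e`), with seeded sub-ring jitter making every vertex's
#' eccentricity unique. Each ring carries equally spaced polar-angle spokes
#' covering the contralateral hemifield, plus two border columns per side
#' just beyond the vertical meridian flagged as non-V1 (standing in for the
#' V1/V2 boundary and exercising non-V1 pruning). The left visual hemifield
#' maps to the right hemisphere and vice versa. The mesh is a regular
#' ring-by-spoke triangulation, hence connected by construction.
#'
#' Polar angle convention: `angle_deg` is the field polar angle
#' `atan2(y, x)` in degrees, 0 at the right horizontal meridian, positive
#' counterclockwise (recorded in the surface metadata).
#'
#' @param spec a [surface_spec()].
#' @return Object of class `retino_surface`: list with `vertices` (data
#'   frame: `vertex_id`, `hemi`, `ecc_deg`, `angle_deg`, `x_deg`, `y_deg`,
#'   `v1_flag`), `triangles` (data frame `v1`, `v2`, `v3` of global vertex
#'   ids), `adjacency` (list of integer neighbor vectors) and `meta`.
#' @export
gen_surface <- function(spec = surface_spec()) {
  stopifnot(inherits(spec, "surface_spec"))
  n <- spec$n_vertices_per_hemi
  e0 <- spec$magnification_e0_deg
  emax <- spec$max_ecc_deg
  n_rings <- max(6L, as.integer(round(sqrt(n / 2))))
  n_spokes <- max(8L, as.integer(round(n / n_rings)))
  if (n_rings < 2L || n_spokes < 2L)
    vf_stop("generation_error", "too few vertices to triangulate")
  ring_ecc <- radial_quantile((seq_len(n_rings) - 0.5) / n_rings, e0, emax)
  gap <- diff(radial_quantile((0:n_rings) / n_rings, e0, emax))
  ncol_tot <- n_spokes + 4L  # two non-V1 border columns each side
  dphi <- 180 / n_spokes
  # hemifield angle of each column center; columns -1,0 and S+1,S+2 are border
  col_idx <- seq_len(ncol_tot) - 2L
  psi0 <- -90 + (col_idx - 0.5) * dphi

  build_hemi <- function(hemi, id0) {
    jit <- with_seed(derive_seed(spec$seed, paste0("surf_", hemi)), {
      list(de = stats::runif(n_rings * ncol_tot, -0.4, 0.4),
           dpsi = stats::runif(n_rings * ncol_tot, -0.3, 0.3))
    })
    r <- rep(seq_len(n_rings), times = ncol_tot)
    ecc <- ring_ecc[r] + jit$de * gap[r]
    ecc <- pmin(pmax(ecc, 1e-4), emax)
    psi <- rep(psi0, each = n_rings) + jit$dpsi * dphi
    # contralateral mapping: lh represents the right hemifield (x > 0)
    phi <- if (hemi == "lh") psi else 180 - psi
    phi <- ((phi + 180) %% 360) - 180
    v1 <- rep(col_idx >= 1L & col_idx <= n_spokes, each = n_rings)
    nv <- n_rings * ncol_tot
    verts <- data.frame(
      vertex_id = id0 + seq_len(nv), hemi = hemi,
      ecc_deg = ecc, angle_deg = phi,
      x_deg = ecc * cos(deg2rad(phi)), y_deg = ecc * sin(deg2rad(phi)),
      v1_flag = v1)
    # triangulate the n_rings x ncol_tot grid (column-major vertex layout)
    vid <- function(rr, cc) id0 + (cc - 1L) * n_rings + rr
    rr <- rep(seq_len(n_rings - 1L), times = ncol_tot - 1L)
    cc <- rep(seq_len(ncol_tot - 1L), each = n_rings - 1L)
    tri <- rbind(
      data.frame(v1 = vid(rr, cc), v2 = vid(rr + 1L, cc),
                 v3 = vid(rr, cc + 1L)),
      data.frame(v1 = vid(rr + 1L, cc), v2 = vid(rr + 1L, cc + 1L),
                 v3 = vid(rr, cc + 1L)))
    list(vertices = verts, triangles = tri)
  }

  lh <- build_hemi("lh", 0L)
  rh <- build_hemi("rh", nrow(lh$vertices))
  vertices <- rbind(lh$vertices, rh$vertices)
  triangles <- rbind(lh$triangles, rh$triangles)
  structure(list(vertices = vertices, triangles = triangles,
                 adjacency = build_adjacency(triangles, nrow(vertices)),
                 meta = list(spec = spec, n_rings = n_rings,
                             n_spokes = n_spokes,
                             n_per_hemi = n_rings * ncol_tot,
                             angle_convention =
                               "field polar angle atan2(y,x), degrees")),
            class = "retino_surface")
}

# symmetric vertex -> neighbor list from a triangle table
build_adjacency <- function(triangles, n_vertices) {
  a <- c(triangles$v1, triangles$v2, triangles$v1)
  b <- c(triangles$v2, triangles$v3, triangles$v3)
  lo <- pmin(a, b); hi <- pmax(a, b)
  keep <- !duplicated((lo - 1) * as.double(n_vertices) + hi)
  lo <- lo[keep]; hi <- hi[keep]
  unname(split(c(hi, lo), factor(c(lo, hi), levels = seq_len(n_vertices))))
}

#' @export
print.retino_surface <- function(x, ...) {
  v <- x$vertices
  cat(sprintf("<retino_surface> %d vertices (%d V1), %d triangles, ecc %.2g-%.3g deg\n",
              nrow(v), sum(v$v1_flag), nrow(x$triangles),
              min(v$ecc_deg), max(v$ecc_deg)))
  if (!is.null(v$thickness_mm))
    cat("  metrics: thickness_mm, ficvf, odi",
        if (!is.null(v$thickness_norm)) "+ thickness_norm", "\n")
  invisible(x)
}

#' Per-vertex validity mask
#'
#' Default exclusion rule applied before ROI aggregation: vertices with
#' non-finite or non-positive metric values (when metrics are present) are
#' invalid.
#'
#' @param surface a `retino_surface`.
#' @return Logical vector over vertices.
#' @export
valid_vertices <- function(surface) {
  v <- surface$vertices
  ok <- rep(TRUE, nrow(v))
  if (!is.null(v$thickness_mm))
    ok <- ok & is.finite(v$thickness_mm) & v$thickness_mm > 0
  for (m in c("ficvf", "odi"))
    if (!is.null(v[[m]])) ok <- ok & is.finite(v[[m]])
  ok
}
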