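# Plain-CSV I/O for every format the pipeline reads and writes.
# Headers are documented here and checked by validate_inputs().

read_csv_checked <- function(path, required) {
  if (!file.exists(path))
    vf_stop("io_error", "file not found: %s", path)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e)
                   vf_stop("io_error", "cannot parse %s: %s", path,
                           conditionMessage(e)))
  missing <- setdiff(required, names(df))
  if (length(missing))
    vf_stop("schema_error", "%s lacks column(s): %s", path,
            paste(missing, collapse = ", "))
  df
}

#' Write a study bundle to a directory of CSV files
#'
#' Files written: `design.csv` (participant, diagnosis, onset, age,
#' acuity_logmar, matched_id), `fixations.csv` (participant, eye, x_deg,
#' y_deg), `sensitivity.csv` (participant, eye, x_deg, y_deg, threshold_db,
#' seen), `surface_vertices.csv` (vertex_id, hemi, ecc_deg, angle_deg,
#' v1_flag), `surface_triangles.csv` (v1, v2, v3), `metrics.csv`
#' (participant, vertex_id, thickness_mm, ficvf, odi).
#'
#' @param bundle a `study_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  stopifnot(inherits(bundle, "study_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, f) utils::write.csv(df, file.path(dir, f),
                                        row.names = FALSE)
  w(bundle$design, "design.csv")
  fx <- do.call(rbind, lapply(names(bundle$participants), function(id) {
    p <- bundle$participants[[id]]
    do.call(rbind, lapply(c("left", "right"), function(e)
      data.frame(participant = id, eye = e,
                 x_deg = p$fixations[[e]]$points[, 1],
                 y_deg = p$fixations[[e]]$points[, 2])))
  }))
  w(fx, "fixations.csv")
  sn <- do.call(rbind, lapply(names(bundle$participants), function(id) {
    p <- bundle$participants[[id]]
    do.call(rbind, lapply(c("left", "right"), function(e)
      cbind(participant = id, eye = e,
            as.data.frame(p$sensitivity[[e]]))))
  }))
  w(sn, "sensitivity.csv")
  w(bundle$surface$vertices[, c("vertex_id", "hemi", "ecc_deg", "angle_deg",
                                "v1_flag")],
    "surface_vertices.csv")
  w(bundle$surface$triangles, "surface_triangles.csv")
  mt <- do.call(rbind, lapply(names(bundle$participants), function(id)
    cbind(participant = id, bundle$participants[[id]]$metrics)))
  w(mt, "metrics.csv")
  invisible(dir)
}

#' Read a study bundle written by [write_cohort()]
#'
#' @param dir directory containing the cohort CSV files.
#' @return A `study_bundle`.
#' @export
read_cohort <- function(dir) {
  design <- read_csv_checked(file.path(dir, "design.csv"),
                             c("participant", "diagnosis", "onset", "age",
                               "acuity_logmar", "matched_id"))
  verts <- read_csv_checked(file.path(dir, "surface_vertices.csv"),
                            c("vertex_id", "hemi", "ecc_deg", "angle_deg",
                              "v1_flag"))
  verts$v1_flag <- as.logical(verts$v1_flag)
  verts$x_deg <- verts$ecc_deg * cos(deg2rad(verts$angle_deg))
  verts$y_deg <- verts$ecc_deg * sin(deg2rad(verts$angle_deg))
  tri <- read_csv_checked(file.path(dir, "surface_triangles.csv"),
                          c("v1", "v2", "v3"))
  surface <- structure(list(vertices = verts, triangles = tri,
                            adjacency = build_adjacency(tri, nrow(verts)),
                            meta = list(source = dir)),
                       class = "retino_surface")
  fx <- read_csv_checked(file.path(dir, "fixations.csv"),
                         c("participant", "eye", "x_deg", "y_deg"))
  sn <- read_csv_checked(file.path(dir, "sensitivity.csv"),
                         c("participant", "eye", "x_deg", "y_deg",
                           "threshold_db", "seen"))
  mt <- read_csv_checked(file.path(dir, "metrics.csv"),
                         c("participant", "vertex_id", "thickness_mm",
                           "ficvf", "odi"))
  participants <- stats::setNames(lapply(design$participant, function(id) {
    fix <- lapply(c(left = "left", right = "right"), function(e) {
      sel <- fx$participant == id & fx$eye == e
      fixation_cloud(fx[sel, c("x_deg", "y_deg")], eye = e)
    })
    sen <- lapply(c(left = "left", right = "right"), function(e) {
      sel <- sn$participant == id & sn$eye == e
      sensitivity_map(sn[sel, c("x_deg", "y_deg", "threshold_db", "seen")],
                      eye = e)
    })
    list(fixations = fix, sensitivity = sen, better_eye = "left",
         metrics = mt[mt$participant == id,
                      c("vertex_id", "thickness_mm", "ficvf", "odi")])
  }), design$participant)
  structure(list(design = design, surface = surface,
                 participants = participants),
            class = "study_bundle")
}

#' Validate a cohort directory
#'
#' Schema check of all CSVs plus cross-file referential integrity:
#' participants present everywhere, `matched_id` resolvable, at least three
#' fixation points per eye.
#'
#' @param dir cohort directory.
#' @return Data frame of violations (`file`, `problem`); zero rows when the
#'   inputs are clean.
#' @export
validate_inputs <- function(dir) {
  schemas <- list(
    design.csv = c("participant", "diagnosis", "onset", "age",
                   "acuity_logmar", "matched_id"),
    fixations.csv = c("participant", "eye", "x_deg", "y_deg"),
    sensitivity.csv = c("participant", "eye", "x_deg", "y_deg",
                        "threshold_db", "seen"),
    surface_vertices.csv = c("vertex_id", "hemi", "ecc_deg", "angle_deg",
                             "v1_flag"),
    surface_triangles.csv = c("v1", "v2", "v3"),
    metrics.csv = c("participant", "vertex_id", "thickness_mm", "ficvf",
                    "odi"))
  bad <- data.frame(file = character(0), problem = character(0))
  note <- function(bad, f, msg)
    rbind(bad, data.frame(file = f, problem = msg))
  tabs <- list()
  for (f in names(schemas)) {
    path <- file.path(dir, f)
    if (!file.exists(path)) { bad <- note(bad, f, "file missing"); next }
    df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                   error = function(e) NULL)
    if (is.null(df)) { bad <- note(bad, f, "unparseable"); next }
    missing <- setdiff(schemas[[f]], names(df))
    if (length(missing)) {
      bad <- note(bad, f, paste("missing column(s):",
                                paste(missing, collapse = ", ")))
      next
    }
    tabs[[f]] <- df
  }
  d <- tabs$design.csv
  if (!is.null(d)) {
    unresolved <- setdiff(stats::na.omit(d$matched_id), d$participant)
    for (u in unresolved)
      bad <- note(bad, "design.csv",
                  sprintf("matched_id '%s' not a participant", u))
    if (!is.null(tabs$metrics.csv)) {
      absent <- setdiff(d$participant, tabs$metrics.csv$participant)
      for (a in absent)
        bad <- note(bad, "metrics.csv",
                    sprintf("participant '%s' has no metric rows", a))
    }
    if (!is.null(tabs$fixations.csv)) {
      fx <- tabs$fixations.csv
      cnt <- stats::aggregate(x_deg ~ participant + eye, fx, length)
      few <- cnt[cnt$x_deg < 3, , drop = FALSE]
      for (i in seq_len(nrow(few)))
        bad <- note(bad, "fixations.csv",
                    sprintf("participant '%s' eye '%s' has %d fixation points (minimum 3)",
                            few$participant[i], few$eye[i], few$x_deg[i]))
    }
  }
  bad
}

#' Published MD-cohort demographic table
#'
#' Demographic and ophthalmic measures (age, onset group, visual acuity in
#' logMAR, PRL eccentricity and 63% BCEA size) for a 20-participant macular
#' degeneration cohort, shipped as a plain-text fixture.
#'
#' @return Data frame with one row per MD participant.
#' @export
md_demographics <- function() {
  path <- system.file("extdata", "md_demographics.csv",
                      package = "vf2cortex", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
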