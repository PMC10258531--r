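# Shared fixtures, memoized so expensive surfaces build once per test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, .fixture_env)) assign(key, builder(), .fixture_env)
  get(key, .fixture_env)
}

test_surface <- function(n = 1000, seed = 2) {
  memo(sprintf("surf_%d_%d", n, seed),
       function() gen_surface(surface_spec(n, seed = seed)))
}

# fully seeing fused sensitivity map
seeing_map <- function() {
  memo("seeing", function()
    overlay_eyes(gen_sensitivity_map(0, seed = 1, eye = "left"),
                 gen_sensitivity_map(0, seed = 2, eye = "right")))
}

# a circular-disc ROI as a vf_roi raster (center, radius in degrees)
disc_roi <- function(center, radius, step = 0.1, role = "PRL") {
  dim <- as.integer(ceiling(2 * (radius + step) / step))
  origin <- center - dim * step / 2
  cc <- vf2cortex:::cell_centers(origin, step, c(dim, dim))
  mask <- (cc[, 1] - center[1])^2 + (cc[, 2] - center[2])^2 <= radius^2
  vf2cortex:::new_vf_roi(role, origin, step, c(dim, dim), mask,
                         center = center)
}

# long metric table simulated directly at participant level (fast path for
# stats-module tests that do not need the surface machinery)
sim_metric_table <- function(n_per_cell, k_within = 2, seed = 1,
                             effects = list()) {
  set.seed(seed)
  cells <- expand.grid(diagnosis = c("MD", "HC"),
                       onset = c("early", "late"),
                       idx = seq_len(n_per_cell),
                       stringsAsFactors = FALSE)
  rois <- paste0("roi", seq_len(k_within))
  do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    base <- rnorm(1, 0, 0.5)
    e <- 0
    if (!is.null(effects$diagnosis))
      e <- e + (effects$diagnosis / 2) * (if (cells$diagnosis[i] == "MD") 1 else -1)
    if (!is.null(effects$interaction))
      e <- e + (effects$interaction / 2) *
        (if (cells$diagnosis[i] == "MD") 1 else -1) *
        (if (cells$onset[i] == "early") 1 else -1)
    data.frame(participant = sprintf("p%03d", i),
               diagnosis = cells$diagnosis[i], onset = cells$onset[i],
               roi_label = rois,
               value = base + e + rnorm(k_within, 0, 1))
  }))
}

# BFS distances over the surface adjacency from a seed set (oracle for
# one-ring dilation): returns integer distance per vertex id (Inf if
# unreachable), restricted to allowed ids
bfs_layers <- function(surface, seed_ids, allowed_ids) {
  nv <- nrow(surface$vertices)
  dist <- rep(Inf, nv)
  allowed <- rep(FALSE, nv); allowed[allowed_ids] <- TRUE
  frontier <- intersect(seed_ids, which(allowed | seq_len(nv) %in% seed_ids))
  dist[frontier] <- 0
  d <- 0
  while (length(frontier)) {
    nb <- unique(unlist(surface$adjacency[frontier], use.names = FALSE))
    nb <- nb[allowed[nb] & !is.finite(dist[nb])]
    d <- d + 1
    dist[nb] <- d
    frontier <- nb
  }
  dist
}
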