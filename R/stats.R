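# Group inference battery: Welch t, three-way mixed ANOVA / ANCOVA with
# Type III sums of squares, Mauchly sphericity test with Greenhouse-Geisser
# and Huynh-Feldt epsilons, and Benjamini-Hochberg post-hocs.
#
# The mixed ANOVA uses the classical split-plot decomposition through a
# multivariate linear model on the wide participant x within-level matrix:
# between-participant effects are tested on the participant means
# (participant error stratum), within and mixed effects on orthonormal
# within-level contrasts (participant x within stratum).

#' Welch two-sample t-test
#'
#' Unequal-variance t with Welch-Satterthwaite degrees of freedom and
#' two-sided p. The subtraction order (`a - b`) is explicit and recorded.
#'
#' @param a,b numeric samples (n >= 2 each).
#' @param names length-2 labels for the two samples.
#' @return Object of class `welch_t`: `t`, `df`, `p`, group `means`, `sds`
#'   (n-1 denominator), `n`, and `direction`.
#' @export
welch_t <- function(a, b, names = c("a", "b")) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    vf_stop("invalid_parameter", "each sample needs n >= 2")
  if (anyNA(a) || anyNA(b))
    vf_stop("invalid_parameter", "samples must not contain NA")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0)
    vf_stop("degenerate_test", "zero variance in both samples")
  na <- length(a); nb <- length(b)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  structure(list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
                 means = stats::setNames(c(mean(a), mean(b)), names),
                 sds = stats::setNames(c(stats::sd(a), stats::sd(b)), names),
                 n = stats::setNames(c(na, nb), names),
                 direction = sprintf("%s - %s", names[1], names[2])),
            class = "welch_t")
}

#' @export
print.welch_t <- function(x, ...) {
  cat(sprintf("Welch t (%s): t = %.3f, df = %.2f, p = %.4g\n",
              x$direction, x$t, x$df, x$p))
  cat(sprintf("  %s: mean %.3f (sd %.3f, n %d); %s: mean %.3f (sd %.3f, n %d)\n",
              names(x$means)[1], x$means[1], x$sds[1], x$n[1],
              names(x$means)[2], x$means[2], x$sds[2], x$n[2]))
  invisible(x)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p vector of raw p-values.
#' @return Adjusted p-values (monotone in the raw ordering, capped at 1).
#' @export
bh_adjust <- function(p) {
  m <- length(p)
  if (!m) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(p[o] * m / rev(seq_len(m))))
  adj[order(o)]
}

# orthonormal contrast matrix (k x k-1), columns orthogonal to the constant
orthonormal_contrasts <- function(k) {
  qr.Q(qr(cbind(1, stats::contr.helmert(k))))[, -1L, drop = FALSE]
}

#' Mauchly's sphericity test and epsilon corrections
#'
#' Computes Mauchly's W from the orthonormalized within-level covariance,
#' its chi-square approximation p-value, the Greenhouse-Geisser epsilon and
#' the Huynh-Feldt epsilon (split-plot form, capped at 1).
#'
#' @param S k x k covariance matrix of the within-level measures (e.g. the
#'   pooled residual covariance).
#' @param n number of participants.
#' @param k number of within levels (>= 3).
#' @param g number of between-participant design cells (1 for a one-group
#'   design); the error degrees of freedom are `n - g`.
#' @return List with `W`, `p`, `epsilon_gg`, `epsilon_hf`.
#' @export
mauchly_and_hf <- function(S, n, k = ncol(S), g = 1) {
  S <- as.matrix(S)
  if (k < 3L) vf_stop("invalid_parameter", "need k >= 3 within levels")
  if (!isTRUE(all.equal(dim(S), c(k, k))))
    vf_stop("invalid_parameter", "S must be k x k")
  M <- orthonormal_contrasts(k)
  mauchly_hf_ortho(crossprod(M, S %*% M), n = n, g = g,
                   scale = mean(diag(S)))
}

# core computation on the already-orthonormalized (k-1)x(k-1) covariance;
# `scale` is the magnitude of the untransformed covariance, used to detect
# singularity of contrasts (e.g. a rank-one compound matrix)
mauchly_hf_ortho <- function(Ss, n, g, scale = mean(diag(Ss))) {
  m <- ncol(Ss)
  dfe <- n - g
  ev <- eigen(Ss, symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) <= 0 || min(ev) <= 1e-12 * max(ev) ||
      max(ev) <= 1e-12 * max(scale, .Machine$double.xmin))
    vf_stop("singular_matrix", "singular within-level covariance")
  W <- prod(ev) / (mean(ev))^m
  # chi-square approximation with Box's second-order correction
  rho <- 1 - (2 * m^2 + m + 2) / (6 * m * dfe)
  w2 <- (m + 2) * (m - 1) * (m - 2) * (2 * m^3 + 6 * m^2 + 3 * m + 2) /
    (288 * (dfe * m * rho)^2)
  z <- -dfe * rho * log(W)
  df_chi <- m * (m + 1) / 2 - 1
  p1 <- stats::pchisq(z, df_chi, lower.tail = FALSE)
  p2 <- stats::pchisq(z, df_chi + 4, lower.tail = FALSE)
  gg <- sum(ev)^2 / (m * sum(ev^2))
  # Lecoutre-corrected Huynh-Feldt for g between cells (reduces to the
  # classic one-group formula when g = 1)
  hf <- min(1, ((dfe + 1) * m * gg - 2) / (m * (dfe - m * gg)))
  list(W = W, p = p1 + w2 * (p2 - p1), epsilon_gg = gg, epsilon_hf = hf)
}

# Type III sums of squares by dropping each term's columns from the full
# design (valid with sum-to-zero contrasts). Returns per-term SS and df plus
# the full-model residuals.
type3_ss <- function(X, Y, assign) {
  Y <- as.matrix(Y)
  qr_full <- qr(X)
  if (qr_full$rank < ncol(X))
    vf_stop("collinearity", "design matrix is rank deficient")
  if (kappa(qr.R(qr_full), exact = FALSE) > 1e10)
    vf_stop("collinearity", "design matrix is ill-conditioned")
  res_full <- qr.resid(qr_full, Y)
  sse_full <- crossprod(res_full)
  terms_idx <- sort(unique(assign[assign != 0L]))
  ss <- lapply(terms_idx, function(t) {
    keep <- assign != t
    r <- qr.resid(qr(X[, keep, drop = FALSE]), Y)
    list(H = crossprod(r) - sse_full, df = sum(!keep))
  })
  # the intercept "term" (assign == 0) tested against the zero-intercept model
  keep0 <- assign != 0L
  H0 <- if (any(!keep0)) {
    r <- if (any(keep0)) qr.resid(qr(X[, keep0, drop = FALSE]), Y)
         else Y
    crossprod(r) - sse_full
  } else NULL
  list(terms = terms_idx, ss = ss, intercept = H0, sse = sse_full,
       df_resid = nrow(Y) - qr_full$rank, resid = res_full)
}

# build the between-participant design matrix with sum-to-zero contrasts
between_design <- function(df, between, covariates) {
  for (b in between) df[[b]] <- factor(df[[b]])
  for (cv in covariates) {
    x <- df[[cv]]
    if (!is.numeric(x))
      vf_stop("invalid_parameter", "covariate `%s` must be numeric", cv)
    if (stats::var(x) == 0)
      vf_stop("collinearity", "covariate `%s` has zero variance", cv)
  }
  fterms <- if (length(between))
    paste(between, collapse = " * ") else "1"
  fml <- stats::as.formula(paste("~", paste(c(fterms, covariates),
                                            collapse = " + ")))
  ctr <- stats::setNames(replicate(length(between), "contr.sum",
                                   simplify = FALSE), between)
  mm <- stats::model.matrix(fml, df,
                            contrasts.arg = if (length(between)) ctr)
  list(X = mm, assign = attr(mm, "assign"),
       labels = attr(stats::terms(fml), "term.labels"))
}

#' Mixed (split-plot) ANOVA with sphericity handling
#'
#' Three-way mixed ANOVA: between-participant factors crossed with one
#' within-participant (repeated) factor. Between effects are tested against
#' the participant error stratum (on participant means); the within main
#' effect and its interactions with between factors are tested against the
#' participant-by-within stratum on orthonormal within contrasts. Sums of
#' squares are Type III with sum-to-zero contrasts. For within factors with
#' three or more levels Mauchly's test is computed and, when it rejects at
#' `sphericity_alpha`, the Huynh-Feldt epsilon rescales the within-effect
#' degrees of freedom (the epsilon is reported regardless).
#'
#' @param data long-format data frame.
#' @param dv name of the dependent-variable column.
#' @param within name of the within-participant factor column, or `NULL`
#'   for a purely between-participant ANOVA.
#' @param between character vector of between-participant factor columns.
#' @param id name of the participant id column.
#' @param covariates character vector of participant-level covariate
#'   columns (entered additively; must be constant within participant).
#' @param sphericity_alpha alpha for the conditional Huynh-Feldt
#'   correction (default 0.05).
#' @return Object of class `anova_result`: effect table (`effect`, `F`,
#'   `df_num`, `df_den`, `p`, `correction`) with sphericity diagnostics
#'   (`mauchly_W`, `mauchly_p`, `epsilon_gg`, `epsilon_hf`) and the SS type
#'   in its attributes.
#' @export
mixed_anova <- function(data, dv, within = NULL, between, id = "participant",
                        covariates = character(0),
                        sphericity_alpha = 0.05) {
  data <- as.data.frame(data)
  for (col in c(dv, within, between, id, covariates))
    if (!col %in% names(data))
      vf_stop("invalid_parameter", "column `%s` not found", col)

  # per-participant between-level frame; covariates must be constant in id
  ids <- unique(data[[id]])
  pdat <- data[!duplicated(data[[id]]), c(id, between, covariates),
               drop = FALSE]
  for (cv in covariates) {
    chk <- tapply(data[[cv]], data[[id]], function(x) length(unique(x)))
    if (any(chk > 1L))
      vf_stop("invalid_parameter",
              "covariate `%s` varies within participant", cv)
  }
  cells <- interaction(pdat[between], drop = TRUE)
  if (any(table(cells) < 2L))
    vf_stop("invalid_parameter",
            "need at least 2 participants per between cell")

  if (is.null(within)) {
    cnt <- table(data[[id]])
    if (any(cnt != 1L))
      vf_stop("unbalanced_design", "participant %s has %d rows, expected 1",
              names(cnt)[cnt != 1L][1], cnt[cnt != 1L][1])
    Y <- matrix(data[[dv]][match(pdat[[id]], data[[id]])], ncol = 1)
    k <- 1L
    wl <- NULL
  } else {
    wfac <- factor(data[[within]])
    wl <- levels(wfac)
    k <- length(wl)
    tab <- table(data[[id]], wfac)
    bad <- which(tab != 1L, arr.ind = TRUE)
    if (nrow(bad))
      vf_stop("unbalanced_design",
              "participant %s does not have exactly one row per %s level",
              rownames(tab)[bad[1, 1]], within)
    Y <- matrix(NA_real_, nrow(pdat), k,
                dimnames = list(pdat[[id]], wl))
    Y[cbind(match(data[[id]], pdat[[id]]), match(wfac, wl))] <- data[[dv]]
  }

  des <- between_design(pdat, between, covariates)
  n <- nrow(Y)

  # ---- between-participant stratum: participant means ----
  yb <- rowMeans(Y)
  const_dv <- stats::var(as.numeric(Y)) < .Machine$double.eps
  t3b <- type3_ss(des$X, yb, des$assign)
  mse_b <- sum(t3b$sse) / t3b$df_resid
  eff <- data.frame(effect = character(0), F = numeric(0),
                    df_num = numeric(0), df_den = numeric(0),
                    p = numeric(0), correction = character(0),
                    stringsAsFactors = FALSE)
  add_eff <- function(eff, name, ss, df, mse, dfe, corr = "none", eps = 1) {
    f <- if (mse > 0) (ss / df) / mse else NA_real_
    p <- if (is.finite(f))
      stats::pf(f, df * eps, dfe * eps, lower.tail = FALSE) else NA_real_
    rbind(eff, data.frame(effect = name, F = f, df_num = df * eps,
                          df_den = dfe * eps, p = p, correction = corr,
                          stringsAsFactors = FALSE))
  }
  for (i in seq_along(t3b$terms)) {
    lab <- des$labels[t3b$terms[i]]
    eff <- add_eff(eff, lab, sum(t3b$ss[[i]]$H), t3b$ss[[i]]$df,
                   mse_b, t3b$df_resid)
  }

  sph <- list(W = NA_real_, p = NA_real_, epsilon_gg = NA_real_,
              epsilon_hf = NA_real_)
  if (k >= 2L) {
    # ---- within stratum: orthonormal contrasts ----
    M <- orthonormal_contrasts(k)
    Yw <- Y %*% M
    t3w <- type3_ss(des$X, Yw, des$assign)
    m <- k - 1L
    dfe_w <- t3w$df_resid * m
    mse_w <- sum(diag(t3w$sse)) / dfe_w
    eps <- 1
    corr <- "none"
    if (k >= 3L && t3w$df_resid >= m) {
      g_cells <- nlevels(cells) + length(covariates)
      sph <- tryCatch(
        mauchly_hf_ortho(t3w$sse / t3w$df_resid, n = n, g = g_cells),
        vf2cortex_error = function(e) sph)  # singular: leave diagnostics NA
      if (is.finite(sph$p) && sph$p < sphericity_alpha) {
        eps <- sph$epsilon_hf
        corr <- "HF"
      }
    }
    # intercept column of the within stratum = within main effect
    eff <- add_eff(eff, within, sum(diag(t3w$intercept)), m, mse_w, dfe_w,
                   corr, eps)
    for (i in seq_along(t3w$terms)) {
      lab <- des$labels[t3w$terms[i]]
      if (lab %in% covariates) next  # covariates are between-level tests
      eff <- add_eff(eff, paste(lab, within, sep = ":"),
                     sum(diag(t3w$ss[[i]]$H)), t3w$ss[[i]]$df * m,
                     mse_w, dfe_w, corr, eps)
    }
  }
  if (const_dv) { eff$F <- NA_real_; eff$p <- NA_real_ }
  structure(list(effects = eff, mauchly_W = sph$W, mauchly_p = sph$p,
                 epsilon_gg = sph$epsilon_gg, epsilon_hf = sph$epsilon_hf,
                 ss_type = "III", within = within, between = between,
                 covariates = covariates, n = n, k_within = k,
                 within_levels = wl, flagged_constant = const_dv),
            class = "anova_result")
}

#' Mixed ANCOVA
#'
#' [mixed_anova()] with participant-level covariates entered additively in
#' the design matrix of both strata; covariate F tests appear in the
#' between-participant stratum. Use [prepare_covariates()] for the
#' conventional transforms (log then center for eccentricity, center for
#' ROI size).
#'
#' @inheritParams mixed_anova
#' @return An `anova_result`.
#' @export
mixed_ancova <- function(data, dv, within = NULL, between,
                         id = "participant", covariates,
                         sphericity_alpha = 0.05) {
  if (!length(covariates))
    vf_stop("invalid_parameter", "ANCOVA requires at least one covariate")
  mixed_anova(data, dv, within, between, id, covariates, sphericity_alpha)
}

#' Covariate transforms for the ANCOVA
#'
#' Average ROI eccentricity is log-transformed (better proxy of cortical
#' distance under cortical magnification) and then mean-centered; ROI vertex
#' counts are centered but not logged.
#'
#' @param df data frame.
#' @param ecc name of the eccentricity column (log then center), or NULL.
#' @param size name of the ROI-size column (center only), or NULL.
#' @return `df` with added `<ecc>_logc` / `<size>_c` columns.
#' @export
prepare_covariates <- function(df, ecc = NULL, size = NULL) {
  if (!is.null(ecc)) {
    x <- log(df[[ecc]])
    df[[paste0(ecc, "_logc")]] <- x - mean(x)
  }
  if (!is.null(size)) df[[paste0(size, "_c")]] <- df[[size]] - mean(df[[size]])
  df
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("Mixed ANOVA (Type %s SS): n = %d participants", x$ss_type, x$n))
  if (!is.null(x$within))
    cat(sprintf(", within `%s` (%d levels)", x$within, x$k_within))
  cat("\n")
  if (is.finite(x$mauchly_W))
    cat(sprintf("  Mauchly W = %.4g (p = %.4g), eps_GG = %.3f, eps_HF = %.3f\n",
                x$mauchly_W, x$mauchly_p, x$epsilon_gg, x$epsilon_hf))
  e <- x$effects
  for (i in seq_len(nrow(e)))
    cat(sprintf("  %-28s F(%.4g, %.5g) = %8.4f, p = %.4g%s\n",
                e$effect[i], e$df_num[i], e$df_den[i], e$F[i], e$p[i],
                if (e$correction[i] == "HF") " [HF]" else ""))
  if (isTRUE(x$flagged_constant))
    cat("  note: dependent variable is constant; F statistics undefined\n")
  invisible(x)
}

#' Per-ROI Welch post-hocs with FDR correction
#'
#' Welch t-test of the two `grouping` levels at each ROI, with
#' Benjamini-Hochberg adjustment across the ROI family and significance at
#' `q`.
#'
#' @param data long data frame with one row per participant x ROI.
#' @param dv dependent-variable column.
#' @param grouping two-level factor column (e.g. diagnosis); the first level
#'   minus the second is the recorded direction.
#' @param rois ROIs to test (default: all in `roi_label` order of
#'   appearance).
#' @param roi_col name of the ROI column.
#' @param q FDR level (default 0.05).
#' @return Data frame: `roi`, `t`, `df`, `p`, `p_adj`, `significant`, plus
#'   the per-ROI `welch_t` objects in attribute `tests`.
#' @export
posthoc_fdr <- function(data, dv, grouping, rois = NULL,
                        roi_col = "roi_label", q = 0.05) {
  data <- as.data.frame(data)
  if (is.null(rois)) rois <- unique(data[[roi_col]])
  g <- factor(data[[grouping]])
  if (nlevels(g) != 2L)
    vf_stop("invalid_parameter", "`%s` must have exactly 2 levels", grouping)
  lv <- levels(g)
  tests <- lapply(rois, function(r) {
    sel <- data[[roi_col]] == r
    welch_t(data[[dv]][sel & g == lv[1]], data[[dv]][sel & g == lv[2]],
            names = lv)
  })
  p <- vapply(tests, `[[`, numeric(1), "p")
  adj <- bh_adjust(p)
  out <- data.frame(roi = rois,
                    t = vapply(tests, `[[`, numeric(1), "t"),
                    df = vapply(tests, `[[`, numeric(1), "df"),
                    p = p, p_adj = adj, significant = adj < q,
                    stringsAsFactors = FALSE)
  attr(out, "tests") <- tests
  attr(out, "direction") <- sprintf("%s - %s", lv[1], lv[2])
  out
}
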