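# Residualized Spearman association grids between attention measures (ICV,
# network strengths) and substance-use factor scores across waves, with
# Benjamini-Hochberg FDR control and quintile trajectory summaries.

#' Residualize a vector on covariates
#'
#' OLS residuals of `y` after regression on the covariates (with intercept);
#' residuals are orthogonal to every covariate column.
#'
#' @param y numeric vector.
#' @param covariates data.frame (factors dummy-coded) or NULL (demeans).
#' @export
residualize <- function(y, covariates = NULL) {
  C <- covariate_matrix(covariates, n = length(y))
  drop(project_out(y, C))
}

#' Tie-aware Spearman correlation with a t-approximation p-value
#'
#' @param x,y numeric vectors (n >= 5).
#' @return list with `rho` and `p`.
#' @export
spearman_corr <- function(x, y) {
  if (length(x) != length(y)) stop(invalid_input("length mismatch"))
  n <- length(x)
  if (n < 5L) stop(invalid_input("need at least 5 observations"))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop(invalid_input("constant input to Spearman correlation"))
  }
  rho <- stats::cor(x, y, method = "spearman")
  tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  list(rho = rho, p = 2 * stats::pt(-abs(tstat), df = n - 2))
}

#' Benjamini-Hochberg FDR control
#'
#' Step-up procedure at level `q`; adjusted p-values via
#' [stats::p.adjust()] with `method = "BH"`.
#'
#' @param pvals vector of p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return list with logical `reject` and numeric `p_adjusted`.
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  if (length(pvals) == 0L) {
    return(list(reject = logical(0), p_adjusted = numeric(0)))
  }
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop(invalid_input("p-values outside [0, 1]"))
  }
  adj <- stats::p.adjust(pvals, method = "BH")
  list(reject = adj <= q, p_adjusted = adj)
}

#' Cross-wave association grid
#'
#' For every (measure wave, factor wave) combination, residualizes the
#' measure and the factor score on their wave's covariates and computes the
#' Spearman correlation, then applies one FDR family across the grid.
#'
#' @param measure subjects-by-waves matrix of an attention measure (ICV or a
#'   network strength); rows are matched subjects.
#' @param factor_scores subjects-by-waves matrix of a substance-use factor.
#' @param covariates list of per-wave covariate data.frames (or NULL).
#' @param fdr_q FDR level for the grid family.
#' @param measure_label,factor_label labels carried into the output.
#' @return data.frame with one row per grid cell: wave_x (measure wave),
#'   wave_y (factor wave), rho, p, p_adjusted, significant, n.
#' @export
cross_wave_association_grid <- function(measure, factor_scores,
                                        covariates = NULL, fdr_q = 0.05,
                                        measure_label = "measure",
                                        factor_label = "factor") {
  measure <- as.matrix(measure)
  factor_scores <- as.matrix(factor_scores)
  if (nrow(measure) != nrow(factor_scores)) {
    stop(invalid_input("subjects not matched across measure and factor tables"))
  }
  wx <- ncol(measure); wy <- ncol(factor_scores)
  cells <- expand.grid(wave_x = seq_len(wx), wave_y = seq_len(wy))
  res <- lapply(seq_len(nrow(cells)), function(ci) {
    i <- cells$wave_x[ci]; j <- cells$wave_y[ci]
    x <- measure[, i]; y <- factor_scores[, j]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 20L) stop(invalid_input("fewer than 20 complete cases in a cell"))
    cx <- if (is.null(covariates)) NULL else covariates[[i]][ok, , drop = FALSE]
    cy <- if (is.null(covariates)) NULL else covariates[[j]][ok, , drop = FALSE]
    sc <- spearman_corr(residualize(x[ok], cx), residualize(y[ok], cy))
    data.frame(
      measure = measure_label, factor = factor_label,
      wave_x = i, wave_y = j, rho = sc$rho, p = sc$p, n = sum(ok)
    )
  })
  out <- do.call(rbind, res)
  fdr <- bh_fdr(out$p, q = fdr_q)
  out$p_adjusted <- fdr$p_adjusted
  out$significant <- fdr$reject
  out
}

#' Quintile trajectory summary
#'
#' Splits subjects into five near-equal groups on a baseline measure and
#' returns per-wave means with normal-approximation 95% CIs for the top and
#' bottom quintiles, labelled by sustained-attention polarity (for ICV and
#' positive-network strength, higher values mean lower sustained attention;
#' for negative-network strength the mapping flips).
#'
#' @param baseline numeric baseline measure (e.g. wave-1 ICV).
#' @param outcome subjects-by-waves matrix of the outcome (e.g. TLFB score).
#' @param higher_is_low_attention TRUE for ICV / positive-network strength,
#'   FALSE for negative-network strength.
#' @return data.frame: quintile (1 = bottom, 5 = top), attention label, wave,
#'   mean, ci_lower, ci_upper, n.
#' @export
quintile_trajectories <- function(baseline, outcome,
                                  higher_is_low_attention = TRUE) {
  outcome <- as.matrix(outcome)
  n <- length(baseline)
  if (n < 25L) stop(invalid_input("need at least 25 subjects"))
  if (nrow(outcome) != n) stop(invalid_input("outcome rows must match baseline"))
  if (stats::sd(baseline) == 0) stop(invalid_input("constant baseline measure"))
  rk <- rank(baseline, ties.method = "average")
  # near-equal groups by rank order; heavy ties at a boundary make the split
  # meaningless
  grp <- as.integer(cut(rank(baseline, ties.method = "first"),
                        breaks = stats::quantile(seq_len(n), probs = seq(0, 1, 0.2)),
                        include.lowest = TRUE, labels = FALSE))
  for (b in stats::quantile(rk, probs = c(0.2, 0.4, 0.6, 0.8))) {
    if (mean(abs(rk - b) < 0.5) > 0.4) {
      stop(invalid_input(
        "more than 40% ties at a quintile boundary; consider rank jitter"
      ))
    }
  }
  keep <- c(1L, 5L)
  rows <- lapply(keep, function(g) {
    idx <- grp == g
    low_attention <- (g == 5L) == higher_is_low_attention
    data.frame(
      quintile = g,
      attention = if (low_attention) "Low SA" else "High SA",
      wave = seq_len(ncol(outcome)),
      mean = colMeans(outcome[idx, , drop = FALSE]),
      ci_lower = colMeans(outcome[idx, , drop = FALSE]) -
        1.96 * apply(outcome[idx, , drop = FALSE], 2, stats::sd) / sqrt(sum(idx)),
      ci_upper = colMeans(outcome[idx, , drop = FALSE]) +
        1.96 * apply(outcome[idx, , drop = FALSE], 2, stats::sd) / sqrt(sum(idx)),
      n = sum(idx)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
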