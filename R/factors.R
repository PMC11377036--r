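# Exploratory factor analysis of Timeline-Followback substance-use items:
# sampling adequacy (KMO), Bartlett's sphericity test, principal-component
# extraction, varimax rotation with Kaiser normalization, and regression-
# method factor scores. The reference analysis finds a cigarette+cannabis
# (Cig+CB) factor, an alcohol factor, and - at the later waves - a drug
# factor.

#' Bartlett's test of sphericity
#'
#' chi^2 = -(n - 1 - (2p + 5)/6) * ln|R| with df = p(p-1)/2.
#'
#' @param R correlation matrix.
#' @param n sample size used to compute R.
#' @return list with `chisq`, `df`, `p`.
#' @export
bartlett_sphericity <- function(R, n) {
  R <- as.matrix(R)
  p <- ncol(R)
  if (n <= p) stop(invalid_input("sample size must exceed item count"))
  detR <- det(R)
  if (detR <= 0) stop(invalid_input("correlation matrix has non-positive determinant"))
  chisq <- -(n - 1 - (2 * p + 5) / 6) * log(detR)
  df <- p * (p - 1) / 2
  list(chisq = chisq, df = df, p = stats::pchisq(chisq, df, lower.tail = FALSE))
}

#' Kaiser-Meyer-Olkin sampling adequacy
#'
#' KMO = sum(r^2) / (sum(r^2) + sum(q^2)) over off-diagonal entries, where q
#' are the anti-image partial correlations; the per-item statistic restricts
#' the sums to that item's row. Items with per-item KMO below `flag_below`
#' are flagged for exclusion.
#'
#' @param R correlation matrix.
#' @param flag_below per-item adequacy floor (default 0.5).
#' @return list with `overall`, `per_item`, `flagged`.
#' @export
kmo <- function(R, flag_below = 0.5) {
  R <- as.matrix(R)
  Rinv <- tryCatch(solve(R), error = function(e) {
    stop(invalid_input("singular correlation matrix"))
  })
  s <- 1 / sqrt(diag(Rinv))
  Q <- -Rinv * outer(s, s)
  diag(Q) <- 0
  R0 <- R; diag(R0) <- 0
  r2 <- R0^2; q2 <- Q^2
  overall <- sum(r2) / (sum(r2) + sum(q2))
  per_item <- rowSums(r2) / (rowSums(r2) + rowSums(q2))
  names(per_item) <- colnames(R)
  list(overall = overall, per_item = per_item, flagged = per_item < flag_below)
}

#' Principal-component factor extraction
#'
#' Loadings are eigenvectors scaled by the square roots of the eigenvalues of
#' the correlation matrix; the automatic retention rule keeps components with
#' eigenvalue > 1 (Kaiser rule).
#'
#' @param R correlation matrix.
#' @param n_factors number of factors or "auto".
#' @return list with `loadings`, `eigenvalues`, `n_factors`.
#' @export
efa_principal <- function(R, n_factors = "auto") {
  R <- as.matrix(R)
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) < -1e-8) {
    stop(invalid_input("correlation matrix is not positive semi-definite"))
  }
  k <- if (identical(n_factors, "auto")) sum(e$values > 1) else as.integer(n_factors)
  if (k < 1L || k > ncol(R)) stop(invalid_input("invalid number of factors"))
  L <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(e$values[seq_len(k)], 0)), k)
  rownames(L) <- colnames(R)
  colnames(L) <- paste0("F", seq_len(k))
  list(loadings = L, eigenvalues = e$values, n_factors = k)
}

#' Varimax rotation with Kaiser normalization
#'
#' @param loadings item-by-factor loading matrix.
#' @param kaiser_normalize row-normalize communalities before rotation.
#' @return list with rotated `loadings` and orthogonal `rotmat`.
#' @export
varimax_rotate <- function(loadings, kaiser_normalize = TRUE) {
  loadings <- as.matrix(loadings)
  if (ncol(loadings) < 2L) {
    warning("single factor: identity rotation")
    return(list(loadings = loadings, rotmat = diag(1)))
  }
  k <- ncol(loadings)
  sc <- if (kaiser_normalize) sqrt(rowSums(loadings^2)) else rep(1, nrow(loadings))
  if (any(sc == 0)) sc[sc == 0] <- 1
  Ln <- loadings / sc
  crit <- function(L) sum(apply(L^2, 2, stats::var))
  # stats::varimax's SVD iteration can stall on symmetric saddle points and
  # stops slightly short of the optimum near flat directions, so: rotate from
  # several fixed orthogonal starts, then polish each with closed-form
  # pairwise (Kaiser) angle sweeps, and keep the best criterion value.
  pairwise_polish <- function(Rm) {
    p <- nrow(Ln)
    for (sweep in 1:100) {
      max_theta <- 0
      Z <- Ln %*% Rm
      for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
        u <- Z[, i]^2 - Z[, j]^2
        v <- 2 * Z[, i] * Z[, j]
        num <- 2 * (sum(u * v) - sum(u) * sum(v) / p)
        den <- sum(u^2 - v^2) - (sum(u)^2 - sum(v)^2) / p
        theta <- atan2(num, den) / 4
        if (abs(theta) > 1e-14) {
          G <- diag(k)
          G[i, i] <- G[j, j] <- cos(theta)
          G[j, i] <- sin(theta); G[i, j] <- -sin(theta)
          Rm <- Rm %*% G
          Z <- Ln %*% Rm
        }
        max_theta <- max(max_theta, abs(theta))
      }
      if (max_theta < 1e-12) break
    }
    Rm
  }
  starts <- c(list(diag(k)), lapply(1:6, function(s) {
    A <- matrix(sin(s * 7 + seq_len(k * k) * exp(1)), k, k)
    qr.Q(qr(A))
  }))
  best <- NULL
  for (S0 in starts) {
    v <- stats::varimax(Ln %*% S0, normalize = FALSE, eps = 1e-12)
    Rm <- pairwise_polish(S0 %*% v$rotmat)
    Zc <- crit(Ln %*% Rm)
    if (is.null(best) || Zc > best$crit + 1e-12) {
      best <- list(rotmat = Rm, crit = Zc)
    }
  }
  L <- loadings %*% best$rotmat
  dimnames(L) <- dimnames(loadings)
  list(loadings = L, rotmat = best$rotmat)
}

#' Regression-method factor scores
#'
#' Scores = Z R^{-1} L on standardized items; each factor's scores have mean
#' zero.
#'
#' @param data subjects-by-items matrix (same items the solution was fitted
#'   on; no missing values).
#' @param solution a fitted [efa_pipeline()] solution (or any list with
#'   `loadings` and `R`).
#' @export
factor_scores <- function(data, solution) {
  X <- as.matrix(data)
  if (anyNA(X)) stop(invalid_input("missing item values; screen items upstream"))
  L <- solution$loadings
  if (!identical(colnames(X), rownames(L))) {
    X <- X[, rownames(L), drop = FALSE]
  }
  Z <- scale(X)
  W <- solve(solution$R, L)
  S <- Z %*% W
  colnames(S) <- colnames(L)
  S
}

#' Full exploratory-factor-analysis pipeline for TLFB items
#'
#' Screens items (near-zero SD; per-item KMO below the floor, removed
#' iteratively worst-first), tests sphericity, extracts principal components
#' (Kaiser rule by default), varimax-rotates, and computes regression scores.
#'
#' @param data subjects-by-items count table.
#' @param n_factors "auto" (eigenvalue > 1) or an integer.
#' @param kmo_min per-item adequacy floor.
#' @param cor_method "pearson" (items standardized) or "spearman" for
#'   heavy-tailed counts.
#' @return object of class `factor_solution`.
#' @export
efa_pipeline <- function(data, n_factors = "auto", kmo_min = 0.5,
                         cor_method = c("pearson", "spearman")) {
  cor_method <- match.arg(cor_method)
  X <- as.matrix(data)
  if (is.null(colnames(X))) colnames(X) <- paste0("item", seq_len(ncol(X)))
  dropped <- character()
  sds <- apply(X, 2, stats::sd)
  near_zero <- sds < 1e-8
  if (any(near_zero)) {
    dropped <- c(dropped, colnames(X)[near_zero])
    X <- X[, !near_zero, drop = FALSE]
  }
  repeat {
    R <- stats::cor(X, method = cor_method)
    km <- kmo(R, flag_below = kmo_min)
    if (!any(km$flagged) || ncol(X) <= 3L) break
    worst <- names(which.min(km$per_item))
    dropped <- c(dropped, worst)
    X <- X[, setdiff(colnames(X), worst), drop = FALSE]
  }
  bart <- bartlett_sphericity(R, n = nrow(X))
  ext <- efa_principal(R, n_factors = n_factors)
  rot <- if (ext$n_factors >= 2L) {
    varimax_rotate(ext$loadings)
  } else {
    list(loadings = ext$loadings, rotmat = diag(1))
  }
  sol <- structure(
    list(
      loadings = rot$loadings, unrotated = ext$loadings,
      rotmat = rot$rotmat, eigenvalues = ext$eigenvalues,
      n_factors = ext$n_factors, R = R, kmo = km, bartlett = bart,
      items = colnames(X), dropped_items = dropped
    ),
    class = "factor_solution"
  )
  sol$scores <- factor_scores(X, sol)
  sol
}

#' Which rotated factor do a set of items load on?
#'
#' Returns, for each item, the factor with the largest absolute rotated
#' loading. Used to check e.g. that tobacco and cannabis items co-load.
#'
#' @param solution a `factor_solution`.
#' @param items item names (default all).
#' @export
dominant_factor <- function(solution, items = NULL) {
  L <- solution$loadings
  if (!is.null(items)) L <- L[intersect(items, rownames(L)), , drop = FALSE]
  apply(abs(L), 1, which.max)
}
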