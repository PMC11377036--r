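# Shared internal helpers: condition constructors, design-matrix assembly,
# residualization.

invalid_input <- function(msg, call = sys.call(-1)) {
  structure(
    class = c("sustattn_invalid_input", "error", "condition"),
    list(message = msg, call = call)
  )
}

degenerate_input <- function(msg, call = sys.call(-1)) {
  structure(
    class = c("sustattn_degenerate_input", "error", "condition"),
    list(message = msg, call = call)
  )
}

#' Build a covariate design matrix with an intercept
#'
#' Numeric columns enter as-is; character/factor columns (e.g. scan site) are
#' expanded to treatment-coded dummies with the first level as reference.
#'
#' @param covariates data.frame of covariates, or NULL for intercept-only.
#' @param n number of rows when `covariates` is NULL.
#' @param drop columns to omit (e.g. "site" under leave-site-out CV).
#' @return numeric matrix whose first column is the intercept.
#' @keywords internal
covariate_matrix <- function(covariates, n = NULL, drop = character()) {
  if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0L) {
    if (is.null(n)) stop(invalid_input("n required when covariates are NULL"))
    return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  }
  covariates <- as.data.frame(covariates)
  covariates <- covariates[, setdiff(names(covariates), drop), drop = FALSE]
  if (anyNA(covariates)) stop(invalid_input("covariates contain missing values"))
  cols <- list(`(Intercept)` = rep(1, nrow(covariates)))
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    if (is.numeric(v) || is.logical(v)) {
      cols[[nm]] <- as.numeric(v)
    } else {
      v <- factor(v)
      for (lev in levels(v)[-1]) {
        cols[[paste0(nm, lev)]] <- as.numeric(v == lev)
      }
    }
  }
  do.call(cbind, cols)
}

# Residuals of each column of y after OLS projection on design X (with
# intercept included in X). Errors on rank-deficient X.
project_out <- function(y, X, check_rank = TRUE) {
  qx <- qr(X)
  if (check_rank && qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[seq(qx$rank + 1L, ncol(X))]]
    stop(invalid_input(paste0(
      "singular covariate design; collinear columns: ",
      paste(bad, collapse = ", ")
    )))
  }
  qr.resid(qx, y)
}
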