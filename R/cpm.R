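# Connectome-based predictive modelling (CPM).
#
# Pipeline: (i) feature selection — partial correlation of every edge with the
# phenotype controlling covariates in the training set, keeping edges with
# p < 0.01 split by sign into positive and negative networks; (ii) network
# strength — the sum of a subject's selected edge values, with the combined
# network = positive minus negative strength; (iii) linear prediction —
# phenotype ~ intercept + strength + covariates fitted on the training set and
# applied, coefficients frozen, to the test set. Validation uses repeated
# k-fold (10/5-fold x 50 repeats) or leave-site-out cross-validation,
# consensus edges (selected in >= 95% of folds), permutation inference, and
# frozen-model transfer across timepoints or to an external sample.

#' Vectorize symmetric connectivity matrices into a cohort edge table
#'
#' Edges are the strict upper triangle in column-major order, so edge k maps
#' to the ROI pair (i, j), i < j, given by the `edge_index` table.
#'
#' @param matrices list of `gppi_matrix` objects or square symmetric matrices.
#' @param subject_ids optional ids (default from the matrices or seq).
#' @param wave optional wave label.
#' @return object of class `cohort_edges`: `edges` (subjects x edges),
#'   `edge_index` (i, j per edge), `n_roi`, `subject_ids`, `wave`.
#' @export
vectorize_edges <- function(matrices, subject_ids = NULL, wave = NA) {
  mats <- lapply(matrices, function(m) if (inherits(m, "gppi_matrix")) m$matrix else as.matrix(m))
  n_roi <- ncol(mats[[1]])
  if (any(vapply(mats, function(m) ncol(m) != n_roi || nrow(m) != n_roi, logical(1)))) {
    stop(invalid_input("matrices differ in ROI count"))
  }
  ut <- upper.tri(mats[[1]])
  E <- t(vapply(mats, function(m) m[ut], numeric(sum(ut))))
  if (is.null(subject_ids)) {
    subject_ids <- vapply(seq_along(matrices), function(i) {
      m <- matrices[[i]]
      if (inherits(m, "gppi_matrix")) m$subject_id else paste0("s", i)
    }, character(1))
  }
  idx <- which(ut, arr.ind = TRUE)
  edge_index <- data.frame(edge = seq_len(nrow(idx)), i = idx[, 1], j = idx[, 2])
  structure(
    list(edges = E, edge_index = edge_index, n_roi = n_roi,
         subject_ids = subject_ids, wave = wave),
    class = "cohort_edges"
  )
}

#' Rebuild a symmetric zero-diagonal matrix from an edge vector
#'
#' Inverse of the [vectorize_edges()] mapping for one subject.
#' @param v edge vector (length n_roi*(n_roi-1)/2).
#' @param n_roi atlas size.
#' @export
devectorize_edges <- function(v, n_roi) {
  M <- matrix(0, n_roi, n_roi)
  M[upper.tri(M)] <- v
  M + t(M)
}

as_edge_matrix <- function(edges) {
  if (inherits(edges, "cohort_edges")) edges$edges else as.matrix(edges)
}

#' Edge-wise partial correlations with a phenotype
#'
#' Pearson correlation between each edge and the phenotype after projecting
#' the covariates (with intercept) out of both; p-values from the t
#' distribution with n - 2 - k degrees of freedom (k covariate columns).
#' Zero-variance edges get r = 0, p = 1 and a flag.
#'
#' @param edges `cohort_edges` or subjects-by-edges matrix.
#' @param phenotype numeric vector.
#' @param covariates data.frame (factors dummy-coded) or NULL.
#' @return data.frame with columns edge, r, p, flagged.
#' @export
edge_partial_correlations <- function(edges, phenotype, covariates = NULL) {
  E <- as_edge_matrix(edges)
  n <- nrow(E)
  C <- covariate_matrix(covariates, n = n)
  if (n <= ncol(C) + 3L) stop(invalid_input("too few subjects for covariate count"))
  st <- .partial_r(E, phenotype, C)
  data.frame(edge = seq_len(ncol(E)), r = st$r, p = st$p, flagged = st$flagged)
}

# Fast path: C must already contain an intercept.
.partial_r <- function(E, y, C) {
  if (stats::sd(y) == 0) stop(invalid_input("zero-variance phenotype"))
  qx <- qr(C)
  yr <- qr.resid(qx, y)
  sy <- sqrt(sum(yr^2))
  if (sy < 1e-12 * sqrt(sum(y^2) + 1)) {
    stop(invalid_input("phenotype fully explained by covariates"))
  }
  Er <- qr.resid(qx, E)
  se <- sqrt(colSums(Er^2))
  r <- as.vector(crossprod(Er, yr)) / (se * sy)
  flagged <- !is.finite(r)
  r[flagged] <- 0
  df <- nrow(E) - 2L - (ncol(C) - 1L)
  tstat <- r * sqrt(pmax(df, 1) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = df)
  p[flagged] <- 1
  list(r = r, p = p, flagged = flagged)
}

#' Select positive and negative edge masks
#'
#' @param edge_stats data.frame from [edge_partial_correlations()].
#' @param p_thresh selection threshold (default 0.01).
#' @return list with `positive` and `negative` edge-index vectors (class
#'   `edge_masks`).
#' @export
select_edges <- function(edge_stats, p_thresh = 0.01) {
  sel <- edge_stats$p < p_thresh & !edge_stats$flagged
  structure(
    list(
      positive = edge_stats$edge[sel & edge_stats$r > 0],
      negative = edge_stats$edge[sel & edge_stats$r < 0],
      p_thresh = p_thresh
    ),
    class = "edge_masks"
  )
}

#' Network strength
#'
#' Sum of a subject's edge values over a mask; the combined network is the
#' positive-mask strength minus the negative-mask strength.
#'
#' @param edges `cohort_edges`, matrix, or a single edge vector.
#' @param mask integer edge indices, or an `edge_masks` object with
#'   `network = "combined"` (default when masks are supplied).
#' @param network one of "positive", "negative", "combined" when `mask` is an
#'   `edge_masks` object.
#' @export
network_strength <- function(edges, mask,
                             network = c("combined", "positive", "negative")) {
  E <- if (!inherits(edges, "cohort_edges") && is.null(dim(edges))) {
    matrix(edges, nrow = 1)
  } else {
    as_edge_matrix(edges)
  }
  if (inherits(mask, "edge_masks")) {
    network <- match.arg(network)
    s <- switch(network,
      positive = .mask_sum(E, mask$positive),
      negative = .mask_sum(E, mask$negative),
      combined = .mask_sum(E, mask$positive) - .mask_sum(E, mask$negative)
    )
  } else {
    s <- .mask_sum(E, mask, warn = TRUE)
  }
  if (!inherits(edges, "cohort_edges") && is.null(dim(edges))) s[1] else s
}

.mask_sum <- function(E, idx, warn = FALSE) {
  if (length(idx) == 0L) {
    if (warn) warning("empty edge mask: strength is 0")
    return(rep(0, nrow(E)))
  }
  rowSums(E[, idx, drop = FALSE])
}

.strengths3 <- function(E, masks) {
  pos <- .mask_sum(E, masks$positive)
  neg <- .mask_sum(E, masks$negative)
  cbind(positive = pos, negative = neg, combined = pos - neg)
}

#' Fit the CPM linear model and predict
#'
#' Ordinary least squares of phenotype on intercept + network strength +
#' covariates in the training set; test predictions apply the trained
#' coefficients to the test strength and covariates.
#'
#' @param strength_train,strength_test network strength vectors.
#' @param y_train training phenotype.
#' @param cov_train,cov_test covariate data.frames (or NULL).
#' @return list with `coefficients` and `predicted`.
#' @export
fit_predict_linear <- function(strength_train, y_train, strength_test,
                               cov_train = NULL, cov_test = NULL) {
  Ctr <- covariate_matrix(cov_train, n = length(strength_train))
  Cte <- covariate_matrix(cov_test, n = length(strength_test))
  Xtr <- cbind(Ctr[, 1, drop = FALSE], strength = strength_train, Ctr[, -1, drop = FALSE])
  if (length(y_train) <= ncol(Xtr)) stop(invalid_input("too few training subjects"))
  qx <- qr(Xtr)
  if (qx$rank < ncol(Xtr)) stop(invalid_input("singular CPM design (constant strength?)"))
  beta <- qr.coef(qx, y_train)
  Xte <- cbind(Cte[, 1, drop = FALSE], strength = strength_test, Cte[, -1, drop = FALSE])
  list(coefficients = beta, predicted = drop(Xte %*% beta))
}

# Train-fold fit + test-fold prediction for all three networks, tolerant of
# empty masks (rank-deficient columns are dropped via pivoting).
.fit_pred3 <- function(Str, y, Ste, Ctr, Cte) {
  sapply(colnames(Str), function(net) {
    X <- cbind(Ctr, strength = Str[, net])
    qx <- qr(X)
    beta <- qr.coef(qx, y)
    beta[is.na(beta)] <- 0
    drop(cbind(Cte, strength = Ste[, net]) %*% beta)
  })
}

.make_folds <- function(n, k) {
  sample(rep(seq_len(k), length.out = n))
}

# Pearson r that returns NA (quietly) when either side is constant, e.g. when
# an edge mask came up empty and the network strength is identically zero.
.safe_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Run cross-validated CPM
#'
#' Feature selection and model fitting happen inside training folds only. The
#' reported r per network is the mean over repeats of the correlation between
#' the pooled out-of-fold predictions and the observed phenotype. Consensus
#' edges are reported at two levels: the fraction of all k x n_repeats folds
#' in which an edge was selected (mask at >= `consensus`), and the number of
#' repeats in which it was selected in >= `consensus` of that repeat's folds.
#'
#' @param edges `cohort_edges` or subjects-by-edges matrix.
#' @param phenotype numeric vector.
#' @param covariates data.frame; must contain `site` for leave-site-out.
#' @param scheme "kfold" or "leave_site_out".
#' @param k folds (5 or 10) for the k-fold scheme.
#' @param n_repeats repeats of the random split (50 in the reference
#'   analysis); forced to 1 for leave-site-out, whose folds are fixed.
#' @param p_thresh edge-selection threshold.
#' @param consensus consensus fraction (default 0.95).
#' @param seed RNG seed for the fold splits.
#' @return object of class `cpm_cv`.
#' @export
run_cv <- function(edges, phenotype, covariates = NULL,
                   scheme = c("kfold", "leave_site_out"), k = 10,
                   n_repeats = 50, p_thresh = 0.01, consensus = 0.95,
                   seed = NULL) {
  scheme <- match.arg(scheme)
  E <- as_edge_matrix(edges)
  n <- nrow(E)
  if (length(phenotype) != n) stop(invalid_input("phenotype length mismatch"))
  if (!is.null(seed)) set.seed(seed)

  if (scheme == "leave_site_out") {
    if (is.null(covariates) || is.null(covariates$site)) {
      stop(invalid_input("leave-site-out CV needs a 'site' covariate"))
    }
    site <- factor(covariates$site)
    fold_of <- as.integer(site)
    k <- nlevels(site)
    n_repeats <- 1L
    C <- covariate_matrix(covariates, n = n, drop = "site")
  } else {
    C <- covariate_matrix(covariates, n = n)
  }
  if (scheme == "leave_site_out") {
    tab <- table(fold_of)
    small <- names(tab)[tab <= ncol(C) + 1L]
    if (length(small)) {
      stop(invalid_input(paste0(
        "site(s) too small for the covariate design: ",
        paste(levels(site)[as.integer(small)], collapse = ", ")
      )))
    }
  }

  n_edges <- ncol(E)
  nets <- c("positive", "negative", "combined")
  r_rep <- matrix(NA_real_, n_repeats, 3, dimnames = list(NULL, nets))
  sel_count <- list(positive = numeric(n_edges), negative = numeric(n_edges))
  rep_count <- list(positive = numeric(n_edges), negative = numeric(n_edges))
  total_folds <- 0L
  last_pred <- NULL

  for (rep_i in seq_len(n_repeats)) {
    folds <- if (scheme == "kfold") .make_folds(n, k) else fold_of
    pred <- matrix(NA_real_, n, 3, dimnames = list(NULL, nets))
    rep_sel <- list(positive = numeric(n_edges), negative = numeric(n_edges))
    for (f in seq_len(k)) {
      te <- folds == f
      tr <- !te
      st <- .partial_r(E[tr, , drop = FALSE], phenotype[tr], C[tr, , drop = FALSE])
      masks <- select_edges(
        data.frame(edge = seq_len(n_edges), r = st$r, p = st$p, flagged = st$flagged),
        p_thresh
      )
      rep_sel$positive[masks$positive] <- rep_sel$positive[masks$positive] + 1
      rep_sel$negative[masks$negative] <- rep_sel$negative[masks$negative] + 1
      Str <- .strengths3(E[tr, , drop = FALSE], masks)
      Ste <- .strengths3(E[te, , drop = FALSE], masks)
      pred[te, ] <- .fit_pred3(Str, phenotype[tr], Ste,
                               C[tr, , drop = FALSE], C[te, , drop = FALSE])
    }
    total_folds <- total_folds + k
    sel_count$positive <- sel_count$positive + rep_sel$positive
    sel_count$negative <- sel_count$negative + rep_sel$negative
    thr <- consensus * k - 1e-9
    rep_count$positive <- rep_count$positive + (rep_sel$positive >= thr)
    rep_count$negative <- rep_count$negative + (rep_sel$negative >= thr)
    r_rep[rep_i, ] <- apply(pred, 2, .safe_cor, y = phenotype)
    last_pred <- pred
  }

  frac <- lapply(sel_count, function(x) x / total_folds)
  structure(
    list(
      networks = lapply(nets, function(net) {
        list(r_mean = mean(r_rep[, net]), r_per_repeat = r_rep[, net])
      }) |> stats::setNames(nets),
      selection_fraction = frac,
      consensus_masks = lapply(frac, function(x) which(x >= consensus - 1e-9)),
      repeat_consensus_masks = lapply(rep_count, function(x) {
        which(x >= ceiling(consensus * n_repeats))
      }),
      predicted = last_pred, observed = phenotype,
      config = list(scheme = scheme, k = k, n_repeats = n_repeats,
                    p_thresh = p_thresh, consensus = consensus, seed = seed)
    ),
    class = "cpm_cv"
  )
}

#' @export
print.cpm_cv <- function(x, ...) {
  cat(sprintf("CPM %s CV (k=%d, %d repeats, p<%g):\n",
              x$config$scheme, x$config$k, x$config$n_repeats, x$config$p_thresh))
  for (net in names(x$networks)) {
    cat(sprintf("  %-9s r = %.3f\n", net, x$networks[[net]]$r_mean))
  }
  invisible(x)
}

#' Train a full-sample CPM model
#'
#' Selects edges and fits the linear models on the whole sample; used for
#' frozen-parameter transfer across timepoints or to an external dataset.
#'
#' @inheritParams run_cv
#' @return object of class `cpm_model` with masks and per-network
#'   coefficients.
#' @export
cpm_train <- function(edges, phenotype, covariates = NULL, p_thresh = 0.01) {
  E <- as_edge_matrix(edges)
  C <- covariate_matrix(covariates, n = nrow(E))
  st <- .partial_r(E, phenotype, C)
  masks <- select_edges(
    data.frame(edge = seq_len(ncol(E)), r = st$r, p = st$p, flagged = st$flagged),
    p_thresh
  )
  Str <- .strengths3(E, masks)
  coefs <- lapply(colnames(Str), function(net) {
    X <- cbind(C[, 1, drop = FALSE], strength = Str[, net], C[, -1, drop = FALSE])
    qx <- qr(X)
    b <- qr.coef(qx, phenotype)
    b[is.na(b)] <- 0
    b
  })
  names(coefs) <- colnames(Str)
  structure(
    list(
      masks = masks, coefficients = coefs, p_thresh = p_thresh,
      n_edges = ncol(E),
      covariate_columns = colnames(C)
    ),
    class = "cpm_model"
  )
}

#' Serialize / deserialize a CPM model as JSON
#' @param model a `cpm_model`.
#' @param path file path.
#' @export
write_cpm_model <- function(model, path) {
  out <- unclass(model)
  out$masks <- unclass(out$masks)
  out$coefficients <- lapply(out$coefficients, as.list)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cpm_model
#' @export
read_cpm_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$masks <- structure(
    list(positive = as.integer(m$masks$positive),
         negative = as.integer(m$masks$negative),
         p_thresh = m$masks$p_thresh),
    class = "edge_masks"
  )
  structure(m, class = "cpm_model")
}

#' Apply a frozen CPM model to another sample
#'
#' Transfer mode: network strengths from the frozen masks are pushed through
#' the frozen linear coefficients (the target sample's own covariate values
#' are used); performance is the correlation between predicted and observed
#' phenotype, with a permutation p obtained by shuffling the predicted values.
#' Residual-correlation mode: the covariate-residualized strength is
#' correlated with the phenotype directly.
#'
#' @param model a [cpm_train()] model.
#' @param edges target-sample edges (same atlas/edge mapping).
#' @param phenotype observed target phenotype.
#' @param covariates target covariates (transfer: must match the training
#'   covariate structure; residual mode: regressed out of strength).
#' @param mode "transfer" or "residual_correlation".
#' @param n_perm permutations for the significance of r.
#' @param seed RNG seed.
#' @return per-network list of r, permutation p, predicted and observed.
#' @export
apply_model_across <- function(model, edges, phenotype, covariates = NULL,
                               mode = c("transfer", "residual_correlation"),
                               n_perm = 1000, seed = NULL) {
  mode <- match.arg(mode)
  E <- as_edge_matrix(edges)
  if (ncol(E) != model$n_edges) {
    stop(invalid_input("edge count mismatch: model built on a different atlas"))
  }
  if (!is.null(seed)) set.seed(seed)
  Str <- .strengths3(E, model$masks)
  out <- list()
  for (net in colnames(Str)) {
    if (mode == "transfer") {
      C <- covariate_matrix(covariates, n = nrow(E))
      # align on the training covariate structure; covariates absent in the
      # target wave (e.g. mode-centred PDS after wave 1) enter at 0, their
      # centred reference value
      Cal <- matrix(0, nrow(E), length(model$covariate_columns),
                    dimnames = list(NULL, model$covariate_columns))
      common <- intersect(colnames(C), model$covariate_columns)
      Cal[, common] <- C[, common]
      b <- model$coefficients[[net]]
      X <- cbind(Cal[, 1, drop = FALSE], strength = Str[, net],
                 Cal[, -1, drop = FALSE])
      pred <- drop(X %*% b)
    } else {
      C <- covariate_matrix(covariates, n = nrow(E))
      pred <- drop(project_out(Str[, net], C))
    }
    r_obs <- .safe_cor(pred, phenotype)
    null_r <- vapply(seq_len(n_perm), function(i) {
      .safe_cor(sample(pred), phenotype)
    }, numeric(1))
    out[[net]] <- list(
      r = r_obs,
      p = (1 + sum(null_r >= r_obs)) / (n_perm + 1),
      predicted = pred, observed = phenotype
    )
  }
  out
}

#' Permutation test of CPM predictive performance
#'
#' Shuffles the phenotype-to-connectome correspondence and reruns the whole
#' CV pipeline `n_perm` times; one-sided p = (1 + #{null r >= observed r}) /
#' (n_perm + 1) per network.
#'
#' @inheritParams run_cv
#' @param n_perm number of permutations (values below 100 trigger a warning).
#' @return list with observed `cpm_cv`, null r matrix, and p per network.
#' @export
permutation_test <- function(edges, phenotype, covariates = NULL,
                             scheme = "kfold", k = 10, n_repeats = 1,
                             p_thresh = 0.01, n_perm = 1000, seed = NULL) {
  if (n_perm < 100) warning("n_perm < 100: permutation p will be unstable")
  if (!is.null(seed)) set.seed(seed)
  obs <- run_cv(edges, phenotype, covariates, scheme = scheme, k = k,
                n_repeats = n_repeats, p_thresh = p_thresh)
  nets <- names(obs$networks)
  null_r <- matrix(NA_real_, n_perm, length(nets), dimnames = list(NULL, nets))
  for (b in seq_len(n_perm)) {
    yb <- sample(phenotype)
    cvb <- run_cv(edges, yb, covariates, scheme = scheme, k = k,
                  n_repeats = n_repeats, p_thresh = p_thresh)
    null_r[b, ] <- vapply(cvb$networks, `[[`, numeric(1), "r_mean")
  }
  obs_r <- vapply(obs$networks, `[[`, numeric(1), "r_mean")
  p <- (1 + colSums(null_r >= rep(obs_r, each = n_perm))) / (n_perm + 1)
  list(observed = obs, observed_r = obs_r, null_r = null_r, p = p)
}
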