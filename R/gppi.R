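# Generalized psychophysiological interaction (gPPI) connectivity.
#
# For every ordered ROI pair the seed time series Y is regressed on the target
# series (physiological term), HRF-convolved condition regressors
# (psychological terms), PPI terms built by deconvolving the target to neural
# level, gating it by the condition boxcar, and reconvolving with the HRF,
# plus 36 nuisance regressors and discrete-cosine high-pass columns. The
# go-trials model carries three conditions (successful stop, failed stop, go;
# 8 model coefficients); the successful-stop model carries two (6
# coefficients). The edge value is the PPI coefficient of the condition of
# interest (go / successful stop); the ROI-by-ROI coefficient matrix is
# averaged with its transpose to yield a symmetric matrix with zero diagonal.

#' Construct an ROI time-series container
#'
#' @param data time-by-ROI numeric matrix.
#' @param tr repetition time (s).
#' @param subject_id identifier.
#' @param roi_labels optional atlas labels (default taken from column names).
#' @export
roi_timeseries <- function(data, tr, subject_id = "subj", roi_labels = NULL) {
  data <- as.matrix(data)
  if (anyNA(data)) stop(invalid_input("ROI time series contain missing samples"))
  if (ncol(data) < 2L) stop(invalid_input("need at least 2 ROIs"))
  if (nrow(data) < 50L) stop(invalid_input("need at least 50 time samples"))
  if (is.null(roi_labels)) {
    roi_labels <- colnames(data)
    if (is.null(roi_labels)) roi_labels <- paste0("roi", seq_len(ncol(data)))
  }
  colnames(data) <- roi_labels
  structure(
    list(data = data, tr = tr, subject_id = subject_id, roi_labels = roi_labels),
    class = "roi_timeseries"
  )
}

# Condition boxcars sampled on the TR grid (used for the neural-level product).
psycho_boxcars_tr <- function(events, conditions, n_time, tr) {
  times <- (seq_len(n_time) - 1L) * tr
  sapply(conditions, function(cond) condition_boxcar(events, cond, times))
}

# PPI regressors for one target ROI: deconvolved neural series gated by each
# condition boxcar and reconvolved with the TR-grid HRF kernel.
ppi_regressors <- function(neural, boxcars, kernel_tr) {
  out <- apply(boxcars, 2, function(psy) convolve_causal(neural * psy, kernel_tr))
  colnames(out) <- paste0("ppi_", sub("^psycho_", "", colnames(boxcars)))
  out
}

#' Fit the gPPI model for one seed/target ROI pair
#'
#' @param seed,target numeric BOLD series of equal length.
#' @param events condition event table (onset, duration, condition).
#' @param confounds 9 base nuisance columns (or 36 precomputed).
#' @param tr repetition time (s).
#' @param model "go_trials" or "successful_stop".
#' @param hrf optional `hrf_model`.
#' @return object of class `gppi_pair_fit` with the model coefficients
#'   (intercept, physiological, psychological, PPI terms), residual variance,
#'   and `ppi_edge_value` (PPI(GO) for the go model, PPI(SS) for the stop
#'   model).
#' @export
fit_gppi_pair <- function(seed, target, events, confounds, tr,
                          model = c("go_trials", "successful_stop"),
                          hrf = NULL) {
  model <- match.arg(model)
  if (length(seed) != length(target)) {
    stop(invalid_input("seed and target series differ in length"))
  }
  if (stats::sd(target) == 0) {
    stop(invalid_input("constant target series: physiological regressor collinear"))
  }
  n_time <- length(seed)
  des <- build_design(events, confounds, n_time, tr, model, hrf)
  hrf <- des$hrf
  k_tr <- hrf_kernel_tr(hrf)
  boxcars <- psycho_boxcars_tr(events, des$conditions, n_time, tr)
  colnames(boxcars) <- colnames(des$X)[des$blocks$task]
  neural <- deconvolve_to_neural(target, hrf)
  ppi <- ppi_regressors(neural, boxcars, k_tr)

  X <- cbind(
    des$X[, des$blocks$intercept, drop = FALSE],
    physio = target,
    des$X[, des$blocks$task, drop = FALSE],
    ppi,
    des$X[, des$blocks$nuisance, drop = FALSE],
    des$X[, des$blocks$highpass, drop = FALSE]
  )
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[seq(qx$rank + 1L, ncol(X))]]
    stop(invalid_input(paste0(
      "collinear gPPI design columns: ", paste(bad, collapse = ", ")
    )))
  }
  beta <- qr.coef(qx, seed)
  res <- qr.resid(qx, seed)
  n_model <- 2L + 2L * length(des$conditions)   # 8 for go model, 6 for stop
  edge_term <- if (model == "go_trials") "ppi_go" else "ppi_success"
  structure(
    list(
      coefficients = beta[seq_len(n_model)],
      all_coefficients = beta,
      sigma2 = sum(res^2) / (n_time - qx$rank),
      ppi_edge_value = unname(beta[edge_term]),
      model = model,
      conditions = des$conditions
    ),
    class = "gppi_pair_fit"
  )
}

#' Symmetrize a connectivity matrix
#'
#' Averages a matrix with its transpose and zeroes the diagonal; idempotent.
#' @param M square numeric matrix.
#' @export
symmetrize_matrix <- function(M) {
  S <- (M + t(M)) / 2
  diag(S) <- 0
  S
}

#' Build a subject's symmetric gPPI matrix
#'
#' Runs the pair GLM for every ordered (seed, target) ROI pair. Shared design
#' columns (intercept, task, nuisance, high-pass) are projected out once and
#' the pair-specific columns (target series and its PPI terms) fitted by
#' Frisch-Waugh-Lovell residual regression, which is algebraically identical
#' to the full per-pair OLS. The coefficient matrix M (rows = seeds) is then
#' symmetrized as (M + t(M))/2 with zero diagonal.
#'
#' @param ts an [roi_timeseries()] (or time-by-ROI matrix; then `tr` required).
#' @param events,confounds,model,hrf as in [fit_gppi_pair()].
#' @param tr repetition time, taken from `ts` when it is an `roi_timeseries`.
#' @return object of class `gppi_matrix`: symmetric `matrix`, condition model,
#'   subject id, ROI labels.
#' @export
build_gppi_matrix <- function(ts, events, confounds,
                              model = c("go_trials", "successful_stop"),
                              tr = NULL, hrf = NULL) {
  model <- match.arg(model)
  if (inherits(ts, "roi_timeseries")) {
    Y <- ts$data; tr <- ts$tr
    subject_id <- ts$subject_id; roi_labels <- ts$roi_labels
  } else {
    Y <- as.matrix(ts)
    if (is.null(tr)) stop(invalid_input("tr required for a bare matrix"))
    subject_id <- "subj"
    roi_labels <- colnames(Y)
    if (is.null(roi_labels)) roi_labels <- paste0("roi", seq_len(ncol(Y)))
  }
  n_time <- nrow(Y); n_roi <- ncol(Y)
  des <- build_design(events, confounds, n_time, tr, model, hrf)
  hrf <- des$hrf
  k_tr <- hrf_kernel_tr(hrf)
  boxcars <- psycho_boxcars_tr(events, des$conditions, n_time, tr)
  colnames(boxcars) <- colnames(des$X)[des$blocks$task]

  neural <- deconvolve_to_neural(Y, hrf)
  qs <- qr(des$X)
  Yres <- qr.resid(qs, Y)
  # PPI regressors per condition for all ROIs, residualized on the shared block
  ppi_res <- lapply(seq_along(des$conditions), function(ci) {
    P <- apply(neural, 2, function(z) {
      convolve_causal(z * boxcars[, ci], k_tr)
    })
    qr.resid(qs, P)
  })
  interest <- if (model == "go_trials") {
    1L + which(des$conditions == "go")
  } else {
    1L + which(des$conditions == "stop_success")
  }
  M <- matrix(0, n_roi, n_roi)
  for (j in seq_len(n_roi)) {
    Xj <- cbind(Yres[, j], sapply(ppi_res, function(P) P[, j]))
    XtX <- crossprod(Xj)
    ok <- tryCatch({
      ch <- chol(XtX); TRUE
    }, error = function(e) FALSE)
    if (!ok) {
      stop(invalid_input(paste0(
        "gPPI pair fit failed for target ROI ", roi_labels[j],
        ": singular pair design"
      )))
    }
    beta <- chol2inv(chol(XtX)) %*% crossprod(Xj, Yres)
    M[, j] <- beta[interest, ]
  }
  diag(M) <- 0
  S <- symmetrize_matrix(M)
  dimnames(S) <- list(roi_labels, roi_labels)
  structure(
    list(
      matrix = S, raw = M, condition_model = model,
      subject_id = subject_id, roi_labels = roi_labels
    ),
    class = "gppi_matrix"
  )
}

#' Write / read a gPPI matrix as TSV with a JSON metadata sidecar
#'
#' @param x a `gppi_matrix`.
#' @param path output TSV path; metadata goes to `<path>.json`.
#' @export
write_gppi_matrix <- function(x, path) {
  utils::write.table(x$matrix, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  meta <- list(
    subject_id = x$subject_id, condition_model = x$condition_model,
    roi_labels = x$roi_labels
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_gppi_matrix
#' @export
read_gppi_matrix <- function(path) {
  M <- as.matrix(utils::read.delim(path, check.names = FALSE))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(
    list(
      matrix = M, raw = M, condition_model = meta$condition_model,
      subject_id = meta$subject_id, roi_labels = meta$roi_labels
    ),
    class = "gppi_matrix"
  )
}
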