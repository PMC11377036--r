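# Canonical haemodynamic response model, task/nuisance/high-pass design
# construction, and ridge-regularized deconvolution of BOLD to neural level.

#' Canonical double-gamma haemodynamic response function
#'
#' SPM-style kernel: a gamma density peaking near 5 s minus a scaled gamma
#' undershoot peaking near 15 s, sampled at `tr / oversampling` over 32 s and
#' normalized to unit sum (so convolution preserves the scale of a sustained
#' input).
#'
#' @param tr repetition time in seconds.
#' @param oversampling microtime resolution factor (samples per TR).
#' @param length_s kernel support in seconds.
#' @param peak_delay,undershoot_delay gamma shape parameters (s, unit rate).
#' @param undershoot_ratio peak:undershoot amplitude ratio denominator.
#' @return object of class `hrf_model` with `kernel`, `times`, `dt`, `tr`.
#' @export
canonical_hrf <- function(tr, oversampling = 16L, length_s = 32,
                          peak_delay = 6, undershoot_delay = 16,
                          undershoot_ratio = 6) {
  if (!is.numeric(tr) || length(tr) != 1L || is.na(tr) || tr <= 0) {
    stop(invalid_input("tr must be a single positive number"))
  }
  oversampling <- as.integer(oversampling)
  dt <- tr / oversampling
  times <- seq(0, length_s, by = dt)
  kernel <- stats::dgamma(times, shape = peak_delay, rate = 1) -
    stats::dgamma(times, shape = undershoot_delay, rate = 1) / undershoot_ratio
  kernel <- kernel / sum(kernel)
  structure(
    list(
      kernel = kernel, times = times, dt = dt, tr = tr,
      oversampling = oversampling,
      parameters = list(
        peak_delay = peak_delay, undershoot_delay = undershoot_delay,
        peak_undershoot_ratio = undershoot_ratio, length_s = length_s
      )
    ),
    class = "hrf_model"
  )
}

# Kernel on the TR grid: the microtime kernel integrated over each TR bin
# (the effective kernel when microtime convolution is downsampled to the TR
# grid); sums to 1 like the microtime kernel. Point-sampling at bin starts
# would put the HRF's leading zero on the operator diagonal and make TR-grid
# convolution numerically singular.
hrf_kernel_tr <- function(hrf) {
  os <- hrf$oversampling
  bins <- ceiling(seq_along(hrf$kernel) / os)
  as.vector(tapply(hrf$kernel, bins, sum))
}

# Causal convolution of x with kernel k, truncated to length(x).
convolve_causal <- function(x, k) {
  n <- length(x)
  out <- stats::convolve(x, rev(k), type = "open")[seq_len(n)]
  out
}

#' Discrete cosine basis for high-pass filtering
#'
#' @param n number of time points.
#' @param K number of cosine columns (frequencies 1..K).
#' @return n x K matrix; columns have unit norm.
#' @export
dct_basis <- function(n, K) {
  if (K < 1L) return(matrix(0, n, 0))
  t <- seq_len(n) - 1L
  B <- sapply(seq_len(K), function(k) {
    sqrt(2 / n) * cos(pi * (2 * t + 1) * k / (2 * n))
  })
  matrix(B, nrow = n, ncol = K)
}

#' Number of discrete-cosine high-pass columns for a cutoff
#'
#' @param n_time,tr run length and repetition time.
#' @param cutoff high-pass cutoff period in seconds (default 128 s).
#' @export
n_highpass_cols <- function(n_time, tr, cutoff = 128) {
  floor(2 * n_time * tr / cutoff)
}

# Boxcar for one condition sampled on an arbitrary time grid.
condition_boxcar <- function(events, condition, times) {
  ev <- events[events$condition == condition, , drop = FALSE]
  u <- numeric(length(times))
  for (i in seq_len(nrow(ev))) {
    u[times >= ev$onset[i] & times < ev$onset[i] + ev$duration[i]] <- 1
  }
  u
}

# HRF-convolved task regressors on the TR grid, built at microtime resolution.
task_regressors <- function(events, conditions, n_time, tr, hrf) {
  os <- hrf$oversampling
  micro_t <- (seq_len(n_time * os) - 1L) * hrf$dt
  idx <- (seq_len(n_time) - 1L) * os + 1L
  X <- sapply(conditions, function(cond) {
    u <- condition_boxcar(events, cond, micro_t)
    convolve_causal(u, hrf$kernel)[idx]
  })
  colnames(X) <- paste0("psycho_", sub("^stop_", "", conditions))
  X
}

#' Expand 9 base nuisance signals to the 36-regressor confound block
#'
#' The 36 columns are 9 base signals (3 translations, 3 rotations, mean white
#' matter / CSF / grey matter signals), their backward-difference temporal
#' derivatives (first sample 0), and the squares of all 18.
#'
#' @param base matrix or data.frame with 9 columns (or 36, returned as-is).
#' @export
expand_nuisance <- function(base) {
  base <- as.matrix(base)
  if (ncol(base) == 36L) return(base)
  if (ncol(base) != 9L) {
    stop(invalid_input("nuisance base must have 9 columns (or 36 precomputed)"))
  }
  if (anyNA(base)) stop(invalid_input("nuisance signals contain missing values"))
  d <- rbind(0, diff(base))
  X18 <- cbind(base, d)
  out <- cbind(X18, X18^2)
  nm <- colnames(base)
  if (is.null(nm)) nm <- paste0("nuis", 1:9)
  colnames(out) <- c(nm, paste0(nm, "_d"), paste0(nm, "_sq"), paste0(nm, "_d_sq"))
  out
}

validate_events <- function(events, n_time, tr) {
  needed <- c("onset", "duration", "condition")
  if (!all(needed %in% names(events))) {
    stop(invalid_input("events need columns onset, duration, condition"))
  }
  events <- events[order(events$onset), , drop = FALSE]
  if (any(events$onset + events$duration > n_time * tr + 1e-9)) {
    stop(invalid_input("event extends beyond the run"))
  }
  events
}

#' Build a gPPI design matrix
#'
#' Assembles intercept, HRF-convolved condition regressors (three for the
#' go-trials model: successful stop, failed stop, go; two for the
#' successful-stop model), the 36-column nuisance block, and discrete-cosine
#' high-pass columns for a 128 s cutoff. Errors if the design is rank
#' deficient, naming the collinear columns.
#'
#' @param events data.frame (onset s, duration s, condition in
#'   go/stop_success/stop_fail).
#' @param confounds 9 base nuisance columns (or precomputed 36).
#' @param n_time,tr run length (samples) and repetition time (s).
#' @param model "go_trials" or "successful_stop".
#' @param hrf optional `hrf_model`; default [canonical_hrf()] at `tr`.
#' @param hp_cutoff high-pass cutoff (s).
#' @return list with design matrix `X`, column-block indices, conditions, hrf.
#' @export
build_design <- function(events, confounds, n_time, tr,
                         model = c("go_trials", "successful_stop"),
                         hrf = NULL, hp_cutoff = 128) {
  model <- match.arg(model)
  if (is.null(hrf)) hrf <- canonical_hrf(tr)
  events <- validate_events(events, n_time, tr)
  conditions <- if (model == "go_trials") {
    c("stop_success", "stop_fail", "go")
  } else {
    c("stop_success", "stop_fail")
  }
  task <- task_regressors(events, conditions, n_time, tr, hrf)
  nuis <- expand_nuisance(confounds)
  if (nrow(nuis) != n_time) stop(invalid_input("confound rows != n_time"))
  K <- n_highpass_cols(n_time, tr, hp_cutoff)
  hpf <- dct_basis(n_time, K)
  if (K > 0) colnames(hpf) <- paste0("hpf", seq_len(K))
  X <- cbind(`(Intercept)` = rep(1, n_time), task, nuis, hpf)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[seq(qx$rank + 1L, ncol(X))]]
    stop(invalid_input(paste0(
      "rank-deficient design; collinear columns: ", paste(bad, collapse = ", ")
    )))
  }
  blocks <- list(
    intercept = 1L,
    task = 1L + seq_len(ncol(task)),
    nuisance = 1L + ncol(task) + seq_len(ncol(nuis)),
    highpass = 1L + ncol(task) + ncol(nuis) + seq_len(ncol(hpf))
  )
  list(
    X = X, blocks = blocks, conditions = conditions, model = model,
    hrf = hrf, tr = tr, n_time = n_time
  )
}

# ---- deconvolution -------------------------------------------------------

.deconv_cache <- new.env(parent = emptyenv())

# SVD of (TR-grid convolution operator) x (full DCT basis), cached per
# (n, kernel) pair: deconvolution of every ROI in a run reuses one SVD.
deconv_operator <- function(n, kernel_tr) {
  key <- paste0(n, "_", length(kernel_tr), "_",
                format(sum(kernel_tr * seq_along(kernel_tr)), digits = 17))
  if (!is.null(.deconv_cache[[key]])) return(.deconv_cache[[key]])
  H <- matrix(0, n, n)
  for (j in seq_len(n)) {
    m <- min(n - j + 1L, length(kernel_tr))
    H[j:(j + m - 1L), j] <- kernel_tr[seq_len(m)]
  }
  B <- cbind(rep(sqrt(1 / n), n), dct_basis(n, n - 1L))
  sv <- svd(H %*% B)
  op <- list(B = B, u = sv$u, d = sv$d, v = sv$v, H = H)
  .deconv_cache[[key]] <- op
  op
}

#' Deconvolve a BOLD series to neural level
#'
#' Ridge-regularized least-squares inversion of the HRF convolution operator
#' on a discrete-cosine basis (Gitelman-style), with the ridge weight chosen
#' by generalized cross-validation; ties broken toward the smallest weight so
#' that noiseless input is inverted essentially exactly.
#'
#' @param bold numeric vector or time-by-ROI matrix.
#' @param hrf an `hrf_model` whose `tr` matches the sampling of `bold`.
#' @return neural-level series with the same shape as `bold`.
#' @export
deconvolve_to_neural <- function(bold, hrf) {
  y <- as.matrix(bold)
  n <- nrow(y)
  k_tr <- hrf_kernel_tr(hrf)
  if (n < length(k_tr)) stop(invalid_input("series shorter than HRF support"))
  op <- deconv_operator(n, k_tr)
  d2 <- op$d^2
  uty <- crossprod(op$u, y)                       # n x p
  lambdas <- max(d2) * 10^seq(-14, 1, length.out = 32)
  best_lambda <- rep(lambdas[1], ncol(y))
  best_gcv <- rep(Inf, ncol(y))
  for (lam in lambdas) {
    shrink <- lam / (d2 + lam)
    rss <- colSums((shrink * uty)^2)
    edf <- n - sum(d2 / (d2 + lam))
    gcv <- n * rss / edf^2
    upd <- gcv < best_gcv * (1 - 1e-8)
    best_gcv[upd] <- gcv[upd]
    best_lambda[upd] <- lam
  }
  # GCV degenerates when the residual is at the numerical noise floor
  # (noiseless input): the unregularized inverse is then consistent and exact,
  # so take the smallest candidate weight for those columns.
  shrink0 <- lambdas[1] / (d2 + lambdas[1])
  rel_rss0 <- colSums((shrink0 * uty)^2) / pmax(colSums(uty^2), .Machine$double.xmin)
  best_lambda[rel_rss0 < 1e-14] <- lambdas[1]
  out <- matrix(0, n, ncol(y))
  for (lam in unique(best_lambda)) {
    cols <- which(best_lambda == lam)
    w <- op$v %*% ((op$d / (d2 + lam)) * uty[, cols, drop = FALSE])
    out[, cols] <- op$B %*% w
  }
  dimnames(out) <- dimnames(y)
  if (is.null(dim(bold))) drop(out) else out
}
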