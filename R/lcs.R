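# Three-wave bivariate latent change score (LCS) model.
#
# Constructs x (substance-use factor) and y (attention measure: ICV or a
# network strength) are observed at waves T1-T3. Between adjacent waves the
# latent change is regressed on the previous levels of both constructs:
#
#   Delta x(t -> t+1) = alpha_x + beta_x * x(t) + gamma2 * y(t) + zeta_x
#   Delta y(t -> t+1) = alpha_y + beta_y * y(t) + gamma1 * x(t) + zeta_y
#
# gamma1 is the lagged effect of substance use on attention, gamma2 the
# lagged effect of attention on substance use. Self-feedback (beta), coupling
# (gamma), and change-residual (co)variances are constrained equal across the
# two intervals; the wave-1 means/variances/covariance and the change
# intercepts are free. Covariates (age, sex, site) are regressed out of the
# observed scores before fitting. The 14 free parameters against 27 observed
# first/second moments leave 13 df. Estimation is normal-theory maximum
# likelihood (quasi-Newton with random restarts); standard errors come from
# the inverse observed information; standardized coefficients use the
# model-implied predictor and change-score SDs.

LCS_PARAM_NAMES <- c(
  "mu_x1", "mu_y1", "alpha_x", "alpha_y", "beta_x", "beta_y",
  "gamma1", "gamma2", "log_var_x1", "log_var_y1", "cov_xy1",
  "log_psi_x", "log_psi_y", "psi_xy"
)

lcs_theta_to_params <- function(theta) {
  p <- as.list(theta)
  names(p) <- LCS_PARAM_NAMES
  p$var_x1 <- exp(p$log_var_x1)
  p$var_y1 <- exp(p$log_var_y1)
  p$psi_x <- exp(p$log_psi_x)
  p$psi_y <- exp(p$log_psi_y)
  p
}

#' Build a latent change score model specification
#'
#' Validates the three-wave structure, residualizes covariates out of the
#' observed scores wave by wave (complete cases only), and packages the
#' 6-variable data block in the order (x1, y1, x2, y2, x3, y3).
#'
#' @param x subjects-by-3 matrix of the substance construct.
#' @param y subjects-by-3 matrix of the attention construct.
#' @param covariates NULL, a single data.frame applied at every wave, or a
#'   list of three per-wave data.frames.
#' @param labels optional c(x = ..., y = ...) construct labels.
#' @return object of class `lcs_spec`.
#' @export
build_lcs_spec <- function(x, y, covariates = NULL, labels = NULL) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (ncol(x) != 3L || ncol(y) != 3L) {
    stop(invalid_input("latent change score model requires exactly 3 waves"))
  }
  if (nrow(x) != nrow(y)) stop(invalid_input("x and y subject counts differ"))
  ok <- stats::complete.cases(x, y)
  if (!is.null(covariates) && !is.list(covariates)) covariates <- NULL
  x <- x[ok, , drop = FALSE]; y <- y[ok, , drop = FALSE]
  if (!is.null(covariates)) {
    if (is.data.frame(covariates)) covariates <- list(covariates, covariates, covariates)
    for (w in 1:3) {
      cv <- as.data.frame(covariates[[min(w, length(covariates))]])[ok, , drop = FALSE]
      x[, w] <- residualize(x[, w], cv)
      y[, w] <- residualize(y[, w], cv)
    }
  }
  data6 <- cbind(x1 = x[, 1], y1 = y[, 1], x2 = x[, 2], y2 = y[, 2],
                 x3 = x[, 3], y3 = y[, 3])
  structure(
    list(
      data = data6, n = nrow(data6),
      param_names = LCS_PARAM_NAMES, n_free = length(LCS_PARAM_NAMES),
      labels = labels
    ),
    class = "lcs_spec"
  )
}

#' Model-implied moments of the bivariate LCS
#'
#' Propagates the state (x_t, y_t) through the transition implied by the
#' change equations: x_{t+1} = (1 + beta_x) x_t + gamma2 y_t + alpha_x +
#' zeta_x (and symmetrically for y), giving the implied mean vector and 6x6
#' covariance of (x1, y1, x2, y2, x3, y3).
#'
#' @param params named list with mu_x1, mu_y1, alpha_x, alpha_y, beta_x,
#'   beta_y, gamma1, gamma2, var_x1, var_y1, cov_xy1, psi_x, psi_y, psi_xy.
#' @return list with `mu`, `Sigma`, and `admissible` (FALSE when a variance
#'   is non-positive or a 2x2 block is not positive definite; values are
#'   flagged, not clipped).
#' @export
implied_moments <- function(params) {
  p <- params
  A <- rbind(c(1 + p$beta_x, p$gamma2),
             c(p$gamma1, 1 + p$beta_y))
  a <- c(p$alpha_x, p$alpha_y)
  P1 <- rbind(c(p$var_x1, p$cov_xy1), c(p$cov_xy1, p$var_y1))
  Q <- rbind(c(p$psi_x, p$psi_xy), c(p$psi_xy, p$psi_y))
  admissible <- p$var_x1 > 0 && p$var_y1 > 0 && p$psi_x > 0 && p$psi_y > 0 &&
    (p$var_x1 * p$var_y1 - p$cov_xy1^2) > 0 &&
    (p$psi_x * p$psi_y - p$psi_xy^2) >= 0

  m <- vector("list", 3); P <- vector("list", 3)
  m[[1]] <- c(p$mu_x1, p$mu_y1); P[[1]] <- P1
  for (t in 1:2) {
    m[[t + 1]] <- drop(A %*% m[[t]]) + a
    P[[t + 1]] <- A %*% P[[t]] %*% t(A) + Q
  }
  Sigma <- matrix(0, 6, 6)
  mu <- numeric(6)
  blk <- function(t) (2 * t - 1):(2 * t)
  for (t in 1:3) {
    mu[blk(t)] <- m[[t]]
    Sigma[blk(t), blk(t)] <- P[[t]]
    s <- t
    lag <- diag(2)
    while (s < 3) {
      s <- s + 1
      lag <- A %*% lag
      Sigma[blk(t), blk(s)] <- P[[t]] %*% t(lag)
      Sigma[blk(s), blk(t)] <- t(Sigma[blk(t), blk(s)])
    }
  }
  nm <- c("x1", "y1", "x2", "y2", "x3", "y3")
  dimnames(Sigma) <- list(nm, nm); names(mu) <- nm
  list(mu = mu, Sigma = Sigma, admissible = admissible)
}

# ML discrepancy F = ln|Sigma| + tr(S Sigma^-1) + (m - mu)' Sigma^-1 (m - mu)
# - ln|S| - p, with S the ML (divisor n) sample covariance.
.lcs_fml <- function(theta, S, m, logdetS) {
  p <- lcs_theta_to_params(theta)
  im <- implied_moments(p)
  if (!im$admissible) return(1e10)
  ch <- tryCatch(chol(im$Sigma), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  logdet <- 2 * sum(log(diag(ch)))
  Sinv_S <- chol2inv(ch) %*% S
  d <- m - im$mu
  quad <- drop(crossprod(backsolve(ch, d, transpose = TRUE)))
  val <- logdet + sum(diag(Sinv_S)) + quad - logdetS - 6
  if (!is.finite(val)) return(1e10)
  val
}

.lcs_start <- function(data6) {
  x <- data6[, c("x1", "x2", "x3")]; y <- data6[, c("y1", "y2", "y3")]
  dx <- cbind(x[, 2] - x[, 1], x[, 3] - x[, 2])
  dy <- cbind(y[, 2] - y[, 1], y[, 3] - y[, 2])
  xl <- c(x[, 1], x[, 2]); yl <- c(y[, 1], y[, 2])
  fx <- stats::lm.fit(cbind(1, xl, yl), c(dx))
  fy <- stats::lm.fit(cbind(1, yl, xl), c(dy))
  c(
    mu_x1 = mean(x[, 1]), mu_y1 = mean(y[, 1]),
    alpha_x = unname(fx$coefficients[1]), alpha_y = unname(fy$coefficients[1]),
    beta_x = unname(fx$coefficients[2]), beta_y = unname(fy$coefficients[2]),
    gamma1 = unname(fy$coefficients[3]), gamma2 = unname(fx$coefficients[3]),
    log_var_x1 = log(max(stats::var(x[, 1]), 1e-4)),
    log_var_y1 = log(max(stats::var(y[, 1]), 1e-4)),
    cov_xy1 = stats::cov(x[, 1], y[, 1]),
    log_psi_x = log(max(stats::var(fx$residuals), 1e-4)),
    log_psi_y = log(max(stats::var(fy$residuals), 1e-4)),
    psi_xy = stats::cov(fx$residuals, fy$residuals)
  )
}

#' Fit the bivariate latent change score model by maximum likelihood
#'
#' Minimizes the normal-theory ML discrepancy with `nlminb` from a
#' moment-based start plus `n_restarts - 1` jittered restarts; keeps the best
#' converged solution. Standard errors come from the inverse observed
#' information (numerical Hessian); standardized gamma coefficients use the
#' model-implied SD of the predictor at wave 1 and of the first-interval
#' change score.
#'
#' @param spec an [build_lcs_spec()] object (or a subjects-by-6 matrix in
#'   (x1, y1, x2, y2, x3, y3) order).
#' @param n_restarts random restarts (>= 1).
#' @param seed RNG seed for the restart jitter.
#' @return object of class `lcs_fit`.
#' @export
fit_ml <- function(spec, n_restarts = 5, seed = NULL) {
  if (!inherits(spec, "lcs_spec")) {
    spec <- build_lcs_spec(spec[, c(1, 3, 5)], spec[, c(2, 4, 6)])
  }
  n <- spec$n
  if (n <= spec$n_free + 10L) {
    stop(invalid_input("sample size too small for the free-parameter count"))
  }
  if (!is.null(seed)) set.seed(seed)
  data6 <- spec$data
  S <- stats::cov(data6) * (n - 1) / n
  m <- colMeans(data6)
  logdetS <- determinant(S, logarithm = TRUE)$modulus

  start0 <- .lcs_start(data6)
  best <- NULL
  for (r in seq_len(max(1L, n_restarts))) {
    st <- if (r == 1L) start0 else start0 + stats::rnorm(length(start0), 0, 0.2)
    fit <- tryCatch(
      stats::nlminb(st, .lcs_fml, S = S, m = m, logdetS = logdetS,
                    control = list(iter.max = 1000, eval.max = 2000,
                                   rel.tol = 1e-10)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(best) || best$objective >= 1e9) {
    stop(invalid_input("latent change score model failed to converge"))
  }
  theta <- best$par
  names(theta) <- LCS_PARAM_NAMES
  params <- lcs_theta_to_params(theta)
  im <- implied_moments(params)

  H <- tryCatch(
    stats::optimHess(theta, .lcs_fml, S = S, m = m, logdetS = logdetS),
    error = function(e) NULL
  )
  se <- rep(NA_real_, length(theta))
  vcov_theta <- NULL
  if (!is.null(H)) {
    info <- (n / 2) * H
    vcov_theta <- tryCatch(solve(info), error = function(e) NULL)
    if (!is.null(vcov_theta) && all(diag(vcov_theta) > 0)) {
      se <- sqrt(diag(vcov_theta))
    }
  }
  names(se) <- LCS_PARAM_NAMES

  # standardized cross-lagged couplings (first interval, implied moments)
  sd_x1 <- sqrt(im$Sigma["x1", "x1"]); sd_y1 <- sqrt(im$Sigma["y1", "y1"])
  var_dx <- im$Sigma["x2", "x2"] + im$Sigma["x1", "x1"] - 2 * im$Sigma["x1", "x2"]
  var_dy <- im$Sigma["y2", "y2"] + im$Sigma["y1", "y1"] - 2 * im$Sigma["y1", "y2"]
  std <- list(
    gamma1 = list(
      est = params$gamma1 * sd_x1 / sqrt(var_dy),
      se = se["gamma1"] * sd_x1 / sqrt(var_dy),
      p = 2 * stats::pnorm(-abs(params$gamma1 / se["gamma1"]))
    ),
    gamma2 = list(
      est = params$gamma2 * sd_y1 / sqrt(var_dx),
      se = se["gamma2"] * sd_y1 / sqrt(var_dx),
      p = 2 * stats::pnorm(-abs(params$gamma2 / se["gamma2"]))
    )
  )

  chisq <- (n - 1) * best$objective
  df <- 6 * 9 / 2 - spec$n_free            # 27 moments - 14 free = 13
  structure(
    list(
      theta = theta, params = params, se = se, vcov = vcov_theta,
      std = std, chisq = chisq, df = df, n = n,
      fmin = best$objective, S = S, m = m, implied = im,
      # PORT's false/singular convergence signals tolerance breakdown at an
      # (admissible) optimum; treat it as converged
      converged = im$admissible &&
        (best$convergence == 0 ||
           grepl("false convergence|singular convergence", best$message)),
      optimizer_message = best$message,
      labels = spec$labels
    ),
    class = "lcs_fit"
  )
}

#' @export
print.lcs_fit <- function(x, ...) {
  cat(sprintf(
    "Bivariate latent change score fit (n = %d, chi^2(%d) = %.2f)\n",
    x$n, x$df, x$chisq
  ))
  cat(sprintf("  gamma1 (x -> dy): %.3f (SE %.3f), std %.3f, p = %.3g\n",
              x$params$gamma1, x$se["gamma1"], x$std$gamma1$est, x$std$gamma1$p))
  cat(sprintf("  gamma2 (y -> dx): %.3f (SE %.3f), std %.3f, p = %.3g\n",
              x$params$gamma2, x$se["gamma2"], x$std$gamma2$est, x$std$gamma2$p))
  invisible(x)
}

#' SEM fit indices for an LCS fit
#'
#' CFI against the independence baseline (diagonal covariance, free means),
#' RMSEA = sqrt(max(chi^2 - df, 0) / (df (n - 1))), and SRMR as the root mean
#' square of the correlation-standardized residuals of S vs the implied
#' covariance (lower triangle including the diagonal).
#'
#' @param fit an [fit_ml()] result.
#' @return named vector c(cfi, rmsea, srmr).
#' @export
fit_indices <- function(fit) {
  S <- fit$S; n <- fit$n
  pvar <- ncol(S)
  logdetS <- determinant(S, logarithm = TRUE)$modulus
  f_base <- sum(log(diag(S))) - logdetS     # tr(S D^-1) = p, means saturated
  chisq_b <- (n - 1) * drop(f_base)
  df_b <- pvar * (pvar - 1) / 2
  excess <- max(fit$chisq - fit$df, 0)
  excess_b <- max(chisq_b - df_b, 0)
  cfi <- 1 - excess / max(excess_b, excess, .Machine$double.eps)
  rmsea <- sqrt(excess / (fit$df * (n - 1)))
  D <- sqrt(diag(S))
  resid <- (S - fit$implied$Sigma) / outer(D, D)
  lower <- resid[lower.tri(resid, diag = TRUE)]
  srmr <- sqrt(mean(lower^2))
  c(cfi = cfi, rmsea = rmsea, srmr = srmr)
}

#' Run the 10-model LCS battery
#'
#' Two substance factors (Cig+CB, alcohol) crossed with five attention
#' measures (ICV and the four network strengths) give 10 bivariate models;
#' FDR (q < 0.05) is applied across the battery's 20 cross-lagged p-values.
#' Single-model failures are recorded per cell and the battery continues.
#'
#' @param substance named list of subjects-by-3 matrices (e.g. cigcb,
#'   alcohol).
#' @param attention named list of subjects-by-3 matrices (e.g. icv, and the
#'   go/stop positive/negative network strengths).
#' @param covariates as in [build_lcs_spec()].
#' @param fdr_q FDR level across the battery.
#' @param n_restarts,seed passed to [fit_ml()].
#' @return data.frame in Table-2 layout: one row per (attention, substance)
#'   cell with standardized gamma1/gamma2, SEs, p-values and FDR flags; the
#'   fitted objects are attached as the "fits" attribute.
#' @export
run_battery <- function(substance, attention, covariates = NULL,
                        fdr_q = 0.05, n_restarts = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list(); fits <- list()
  for (att_name in names(attention)) {
    for (sub_name in names(substance)) {
      key <- paste(att_name, sub_name, sep = ".")
      fit <- tryCatch({
        spec <- build_lcs_spec(substance[[sub_name]], attention[[att_name]],
                               covariates = covariates,
                               labels = c(x = sub_name, y = att_name))
        fit_ml(spec, n_restarts = n_restarts)
      }, error = function(e) e)
      fits[[key]] <- fit
      if (inherits(fit, "error")) {
        rows[[key]] <- data.frame(
          attention = att_name, substance = sub_name,
          gamma1_std = NA, gamma1_se = NA, gamma1_p = NA,
          gamma2_std = NA, gamma2_se = NA, gamma2_p = NA,
          converged = FALSE, error = conditionMessage(fit)
        )
      } else {
        rows[[key]] <- data.frame(
          attention = att_name, substance = sub_name,
          gamma1_std = fit$std$gamma1$est, gamma1_se = fit$std$gamma1$se,
          gamma1_p = fit$std$gamma1$p,
          gamma2_std = fit$std$gamma2$est, gamma2_se = fit$std$gamma2$se,
          gamma2_p = fit$std$gamma2$p,
          converged = fit$converged, error = NA_character_
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  pv <- c(out$gamma1_p, out$gamma2_p)
  ok <- !is.na(pv)
  rej <- rep(NA, length(pv))
  if (any(ok)) {
    fdr <- bh_fdr(pv[ok], q = fdr_q)
    rej[ok] <- fdr$reject
  }
  k <- nrow(out)
  out$gamma1_fdr_significant <- rej[seq_len(k)]
  out$gamma2_fdr_significant <- rej[k + seq_len(k)]
  attr(out, "fits") <- fits
  out
}

#' Simulate data from the bivariate LCS generative equations
#'
#' @param n subjects.
#' @param gamma1 lagged effect of x (substance) on the change in y.
#' @param gamma2 lagged effect of y (attention) on the change in x.
#' @param beta_x,beta_y proportional self-feedback of the changes.
#' @param alpha_x,alpha_y change intercepts.
#' @param mu1,var1 wave-1 means and variances c(x, y).
#' @param cov_xy1 wave-1 covariance.
#' @param psi change residual variances c(x, y); `psi_xy` their covariance.
#' @param seed RNG seed.
#' @return list with `x`, `y` (n-by-3 matrices) and the generative `params`.
#' @export
simulate_lcs_data <- function(n, gamma1 = 0, gamma2 = 0.12,
                              beta_x = -0.2, beta_y = -0.2,
                              alpha_x = 0, alpha_y = 0,
                              mu1 = c(0, 0), var1 = c(1, 1), cov_xy1 = 0.3,
                              psi = c(0.25, 0.25), psi_xy = 0.05,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  P1 <- rbind(c(var1[1], cov_xy1), c(cov_xy1, var1[2]))
  Q <- rbind(c(psi[1], psi_xy), c(psi_xy, psi[2]))
  cP <- chol(P1); cQ <- chol(Q)
  s1 <- matrix(stats::rnorm(2 * n), n, 2) %*% cP
  s1 <- sweep(s1, 2, mu1, "+")
  x <- matrix(NA_real_, n, 3); y <- matrix(NA_real_, n, 3)
  x[, 1] <- s1[, 1]; y[, 1] <- s1[, 2]
  for (t in 1:2) {
    z <- matrix(stats::rnorm(2 * n), n, 2) %*% cQ
    dx <- alpha_x + beta_x * x[, t] + gamma2 * y[, t] + z[, 1]
    dy <- alpha_y + beta_y * y[, t] + gamma1 * x[, t] + z[, 2]
    x[, t + 1] <- x[, t] + dx
    y[, t + 1] <- y[, t] + dy
  }
  list(
    x = x, y = y,
    params = list(
      gamma1 = gamma1, gamma2 = gamma2, beta_x = beta_x, beta_y = beta_y,
      alpha_x = alpha_x, alpha_y = alpha_y, mu_x1 = mu1[1], mu_y1 = mu1[2],
      var_x1 = var1[1], var_y1 = var1[2], cov_xy1 = cov_xy1,
      psi_x = psi[1], psi_y = psi[2], psi_xy = psi_xy
    )
  )
}
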