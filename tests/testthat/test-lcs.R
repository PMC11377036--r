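true_theta <- function(p) {
  c(mu_x1 = p$mu_x1, mu_y1 = p$mu_y1, alpha_x = p$alpha_x,
    alpha_y = p$alpha_y, beta_x = p$beta_x, beta_y = p$beta_y,
    gamma1 = p$gamma1, gamma2 = p$gamma2,
    log_var_x1 = log(p$var_x1), log_var_y1 = log(p$var_y1),
    cov_xy1 = p$cov_xy1, log_psi_x = log(p$psi_x), log_psi_y = log(p$psi_y),
    psi_xy = p$psi_xy)
}

as_params <- function(theta) sustattn:::lcs_theta_to_params(theta)

test_that("model specification validates the three-wave structure", {
  d <- simulate_lcs_data(100, seed = 1)
  spec <- build_lcs_spec(d$x, d$y)
  expect_equal(spec$n_free, 14)
  expect_equal(ncol(spec$data), 6)
  expect_error(build_lcs_spec(d$x[, 1:2], d$y[, 1:2]),
               class = "sustattn_invalid_input")
  # free-parameter count against the moment count: df = 27 - 14 = 13
  expect_equal(6 * 7 / 2 + 6 - spec$n_free, 13)
})

test_that("implied moments decouple when the dynamics are switched off", {
  p <- as_params(true_theta(list(
    mu_x1 = 0, mu_y1 = 0, alpha_x = 0, alpha_y = 0, beta_x = -1, beta_y = -1,
    gamma1 = 0, gamma2 = 0, var_x1 = 1, var_y1 = 1, cov_xy1 = 0,
    psi_x = 1, psi_y = 1, psi_xy = 0
  )))
  im <- implied_moments(p)
  expect_true(im$admissible)
  # beta = -1 and gamma = 0: later waves are pure innovations, so every
  # cross-lagged covariance entry vanishes
  expect_equal(im$Sigma["x1", "y2"], 0)
  expect_equal(im$Sigma["y1", "x3"], 0)
  expect_equal(im$Sigma["x2", "y3"], 0)
  # inadmissible values are flagged, not clipped
  p_bad <- p; p_bad$cov_xy1 <- 2
  expect_false(implied_moments(p_bad)$admissible)
})

test_that("implied moments match simulated moments at large n", {
  d <- simulate_lcs_data(200000, gamma1 = 0.05, gamma2 = 0.12, seed = 2)
  th <- true_theta(d$params)
  im <- implied_moments(as_params(th))
  data6 <- cbind(d$x[, 1], d$y[, 1], d$x[, 2], d$y[, 2], d$x[, 3], d$y[, 3])
  expect_equal(colMeans(data6), unname(im$mu), tolerance = 0.02)
  expect_equal(cov(data6), unname(im$Sigma), tolerance = 0.05,
               ignore_attr = TRUE)
})

test_that("the discrepancy is zero at the truth on noise-free moments", {
  p0 <- list(mu_x1 = 0.1, mu_y1 = -0.2, alpha_x = 0.05, alpha_y = 0,
             beta_x = -0.3, beta_y = -0.2, gamma1 = 0.08, gamma2 = 0.12,
             var_x1 = 1, var_y1 = 1.2, cov_xy1 = 0.3, psi_x = 0.25,
             psi_y = 0.3, psi_xy = 0.05)
  th0 <- true_theta(p0)
  im <- implied_moments(as_params(th0))
  logdetS <- determinant(im$Sigma, logarithm = TRUE)$modulus
  f0 <- sustattn:::.lcs_fml(th0, im$Sigma, im$mu, logdetS)
  expect_lt(abs(f0), 1e-10)
  # any perturbation increases the discrepancy
  for (i in c(5, 7, 8, 12)) {
    th <- th0; th[i] <- th[i] + 0.1
    expect_gt(sustattn:::.lcs_fml(th, im$Sigma, im$mu, logdetS), f0 + 1e-6)
  }
})

test_that("ML refit from noise-free implied moments recovers the parameters", {
  p0 <- list(mu_x1 = 0, mu_y1 = 0, alpha_x = 0, alpha_y = 0,
             beta_x = -0.2, beta_y = -0.25, gamma1 = 0.05, gamma2 = 0.12,
             var_x1 = 1, var_y1 = 1, cov_xy1 = 0.3, psi_x = 0.25,
             psi_y = 0.25, psi_xy = 0.05)
  im <- implied_moments(as_params(true_theta(p0)))
  # large synthetic sample drawn exactly from the implied distribution
  set.seed(3)
  L <- chol(im$Sigma)
  data6 <- matrix(rnorm(6 * 50000), 50000, 6) %*% L
  data6 <- sweep(data6, 2, im$mu, "+")
  colnames(data6) <- colnames(im$Sigma)
  fit <- fit_ml(data6, n_restarts = 2, seed = 4)
  expect_lt(abs(fit$params$gamma2 - 0.12), 0.02)
  expect_lt(abs(fit$params$gamma1 - 0.05), 0.02)
  expect_lt(abs(fit$params$beta_x - (-0.2)), 0.03)
})

test_that("coupling estimates and their asymmetry are recovered at n = 1000", {
  res <- t(sapply(1:10, function(s) {
    d <- simulate_lcs_data(1000, gamma1 = 0, gamma2 = 0.12, seed = s)
    f <- fit_ml(build_lcs_spec(d$x, d$y), n_restarts = 3, seed = 600 + s)
    c(g2 = f$params$gamma2, g1 = f$params$gamma1,
      asym = f$params$gamma2 > f$params$gamma1)
  }))
  expect_lt(abs(mean(res[, "g2"]) - 0.12), 0.02)
  expect_lt(abs(mean(res[, "g1"])), 0.02)
  expect_gte(mean(res[, "asym"]), 0.9)
})

test_that("estimator bias shrinks with sample size", {
  bias <- sapply(c(250, 1000, 4000), function(n) {
    errs <- sapply(1:6, function(s) {
      d <- simulate_lcs_data(n, gamma1 = 0.05, gamma2 = 0.12, seed = 10 * n + s)
      f <- fit_ml(build_lcs_spec(d$x, d$y), n_restarts = 2, seed = s)
      abs(f$params$gamma2 - 0.12)
    })
    mean(errs)
  })
  expect_lt(bias[3], bias[1] + 0.01)
  expect_lt(bias[3], 0.02)
})

test_that("standardized coefficients are invariant to observed-variable scaling", {
  d <- simulate_lcs_data(800, gamma1 = 0.05, gamma2 = 0.12, seed = 20)
  f1 <- fit_ml(build_lcs_spec(d$x, d$y), n_restarts = 2, seed = 21)
  f2 <- fit_ml(build_lcs_spec(d$x * 10, d$y), n_restarts = 2, seed = 21)
  expect_equal(f2$std$gamma2$est, f1$std$gamma2$est, tolerance = 1e-4)
  expect_equal(f2$std$gamma1$est, f1$std$gamma1$est, tolerance = 1e-4)
  # unstandardized gamma2 (y -> dx) scales with x
  expect_equal(f2$params$gamma2, 10 * f1$params$gamma2, tolerance = 1e-3)
})

test_that("fit indices behave at their reference points", {
  d <- simulate_lcs_data(1000, seed = 30)
  f <- fit_ml(build_lcs_spec(d$x, d$y), n_restarts = 2, seed = 31)
  fi <- fit_indices(f)
  expect_true(fi["cfi"] >= 0 && fi["cfi"] <= 1)
  expect_gte(fi["rmsea"], 0)
  # perfect fit: feed the model its own implied moments
  f_perfect <- f
  f_perfect$S <- f$implied$Sigma
  f_perfect$m <- f$implied$mu
  f_perfect$chisq <- 0
  fi_p <- fit_indices(f_perfect)
  expect_equal(unname(fi_p["cfi"]), 1)
  expect_equal(unname(fi_p["rmsea"]), 0)
  expect_equal(unname(fi_p["srmr"]), 0)
})

test_that("forcing couplings to zero on coupled data worsens the residuals", {
  d <- simulate_lcs_data(2000, gamma1 = 0.3, gamma2 = 0.3, seed = 40)
  f_free <- fit_ml(build_lcs_spec(d$x, d$y), n_restarts = 2, seed = 41)
  # misspecified fit: projection with gamma frozen at zero via penalized start
  th <- f_free$theta
  th["gamma1"] <- 0; th["gamma2"] <- 0
  S <- f_free$S; m <- f_free$m
  logdetS <- determinant(S, logarithm = TRUE)$modulus
  obj <- function(free_idx) {
    fn <- function(v) {
      tt <- th; tt[free_idx] <- v
      sustattn:::.lcs_fml(tt, S, m, logdetS)
    }
    free_start <- th[free_idx]
    opt <- nlminb(free_start, fn)
    tt <- th; tt[free_idx] <- opt$par
    tt
  }
  idx <- setdiff(seq_along(th), which(names(th) %in% c("gamma1", "gamma2")))
  th_constrained <- obj(idx)
  im_c <- implied_moments(sustattn:::lcs_theta_to_params(th_constrained))
  D <- sqrt(diag(S))
  srmr_c <- sqrt(mean(((S - im_c$Sigma) / outer(D, D))[
    lower.tri(S, diag = TRUE)]^2))
  fi_free <- fit_indices(f_free)
  expect_gt(srmr_c, fi_free["srmr"])
})

test_that("small samples are rejected", {
  d <- simulate_lcs_data(20, seed = 50)
  expect_error(fit_ml(build_lcs_spec(d$x, d$y)),
               class = "sustattn_invalid_input")
})

test_that("the ten-model battery mirrors the Table-2 layout with FDR flags", {
  coh <- simulate_connectome_cohort(
    cohort_config(n_subjects = 600, n_rois = 10, gamma2 = 0.15, seed = 60)
  )
  sub <- simulate_substance_trajectories(coh, seed = 61)
  att <- list(
    icv = sapply(coh$waves, function(w) w$phenotype),
    gt_pos = sub$attention + matrix(rnorm(600 * 3, sd = 0.5), 600, 3),
    gt_neg = -sub$attention + matrix(rnorm(600 * 3, sd = 0.5), 600, 3),
    ss_pos = sub$attention + matrix(rnorm(600 * 3, sd = 0.7), 600, 3),
    ss_neg = -sub$attention + matrix(rnorm(600 * 3, sd = 0.7), 600, 3)
  )
  battery <- run_battery(
    substance = list(cigcb = sub$factors$cigcb, alcohol = sub$factors$alcohol),
    attention = att, n_restarts = 2, seed = 62
  )
  expect_equal(nrow(battery), 10)
  expect_true(all(battery$converged))
  # FDR flags are a subset of raw p < 0.05
  expect_true(all(battery$gamma2_p[battery$gamma2_fdr_significant] < 0.05))
  expect_true(all(battery$gamma1_p[battery$gamma1_fdr_significant] < 0.05))
  # the planted direction: attention -> substance for the Cig+CB factor
  icv_cigcb <- battery[battery$attention == "icv" &
                         battery$substance == "cigcb", ]
  expect_true(icv_cigcb$gamma2_fdr_significant)
})
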