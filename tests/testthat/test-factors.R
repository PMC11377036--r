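two_block_R <- function(p1 = 3, p2 = 3, r_within = 0.7, r_between = 0) {
  p <- p1 + p2
  R <- matrix(r_between, p, p)
  R[seq_len(p1), seq_len(p1)] <- r_within
  R[p1 + seq_len(p2), p1 + seq_len(p2)] <- r_within
  diag(R) <- 1
  colnames(R) <- rownames(R) <- paste0("v", seq_len(p))
  R
}

test_that("Bartlett sphericity matches the closed formula", {
  R6 <- two_block_R()
  b <- bartlett_sphericity(R6, n = 500)
  expect_equal(b$df, 15)                        # six items
  # identity: ln|I| = 0
  b0 <- bartlett_sphericity(diag(6), n = 500)
  expect_equal(b0$chisq, 0)
  expect_equal(b0$p, 1)
  # 2x2, r = 0.5, n = 100: hand evaluation of the formula
  R2 <- matrix(c(1, 0.5, 0.5, 1), 2)
  b2 <- bartlett_sphericity(R2, n = 100)
  expect_equal(b2$chisq, -(100 - 1 - 9 / 6) * log(0.75), tolerance = 1e-12)
  expect_equal(b2$df, 1)
})

test_that("Bartlett chi-square grows with n for a fixed non-identity R", {
  R <- two_block_R()
  chis <- sapply(c(100, 400, 1600), function(n) bartlett_sphericity(R, n)$chisq)
  expect_true(all(diff(chis) > 0))
})

test_that("KMO computes anti-image adequacy and flags isolated items", {
  R <- two_block_R(r_within = 0.7, r_between = 0)
  k <- kmo(R)
  expect_gt(k$overall, 0.6)
  # an item whose raw correlations are dominated by partial ones (a
  # suppressor built from the difference of two correlated items) is
  # inadequate under the anti-image formula
  w <- c(1, -1, 0, 0, 0, 0)
  cov7 <- as.vector(R %*% w) * 0.9 / sqrt(0.6)
  R7 <- rbind(cbind(R, cov7), c(cov7, 1))
  colnames(R7) <- rownames(R7) <- paste0("v", 1:7)
  k7 <- kmo(R7)
  expect_lt(k7$per_item["v7"], 0.5)
  expect_true(k7$flagged["v7"])
  # permutation invariance
  perm <- c(3, 1, 6, 2, 5, 4)
  k_perm <- kmo(R[perm, perm])
  expect_equal(k_perm$overall, k$overall, tolerance = 1e-12)
  expect_equal(unname(k_perm$per_item), unname(k$per_item[perm]),
               tolerance = 1e-12)
})

test_that("principal extraction reproduces eigenstructure", {
  R <- two_block_R(r_within = 0.6)
  e <- efa_principal(R, n_factors = "auto")
  expect_equal(sum(e$eigenvalues), 6, tolerance = 1e-10)  # trace of R
  expect_equal(e$n_factors, 2)
  # full decomposition reproduces R
  full <- efa_principal(R, n_factors = 6)
  expect_equal(full$loadings %*% t(full$loadings), R, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("varimax rotation separates a two-block structure", {
  R <- two_block_R(r_within = 0.6, r_between = 0.1)
  e <- efa_principal(R, 2)
  rot <- varimax_rotate(e$loadings)
  expect_equal(crossprod(rot$rotmat), diag(2), tolerance = 1e-8)
  L <- abs(rot$loadings)
  blk1 <- apply(L[1:3, ], 1, which.max)
  blk2 <- apply(L[4:6, ], 1, which.max)
  expect_length(unique(blk1), 1)
  expect_length(unique(blk2), 1)
  expect_false(blk1[1] == blk2[1])
  expect_true(all(apply(L, 1, max) > 0.6))
  expect_true(all(apply(L, 1, min) < 0.3))
  # communalities preserved
  expect_equal(rowSums(rot$loadings^2), rowSums(e$loadings^2),
               tolerance = 1e-8)
})

test_that("rotated solution beats every rotation on a fine angle grid", {
  R <- two_block_R(r_within = 0.5, r_between = 0.15)
  e <- efa_principal(R, 2)
  rot <- varimax_rotate(e$loadings, kaiser_normalize = FALSE)
  crit_opt <- varimax_criterion(rot$loadings)
  angles <- seq(0, pi / 2, by = 0.1 * pi / 180)
  crit_grid <- sapply(angles, function(a) {
    Rm <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
    varimax_criterion(e$loadings %*% Rm)
  })
  expect_gte(crit_opt, max(crit_grid) - 1e-8)
})

test_that("varimax fixed point returns unchanged loadings", {
  R <- two_block_R(r_within = 0.6)
  rot1 <- varimax_rotate(efa_principal(R, 2)$loadings)
  rot2 <- varimax_rotate(rot1$loadings)
  # already optimal: same up to column sign/permutation
  agree <- abs(crossprod(rot2$rotmat))
  expect_equal(sort(round(agree, 6)), sort(round(diag(2), 6)))
})

test_that("regression scores are centred and recover generative factors", {
  set.seed(9)
  n <- 1000
  f <- matrix(rnorm(2 * n), n, 2)
  L_true <- rbind(c(0.8, 0), c(0.7, 0), c(0.75, 0),
                  c(0, 0.8), c(0, 0.7), c(0, 0.75))
  X <- f %*% t(L_true) + matrix(rnorm(6 * n, sd = 0.5), n, 6)
  colnames(X) <- paste0("v", 1:6)
  sol <- efa_pipeline(X)
  expect_equal(sol$n_factors, 2)
  expect_true(all(abs(colMeans(sol$scores)) < 1e-10))
  # each generative factor matched by some score column
  m <- abs(cor(sol$scores, f))
  expect_gt(max(m[, 1]), 0.8)
  expect_gt(max(m[, 2]), 0.8)
  # duplicating a subject duplicates the score
  sc <- factor_scores(X[c(1, 1, 2:10), ], sol)
  expect_equal(sc[1, ], sc[2, ])
})

test_that("synthetic TLFB recovers the substance factor structure", {
  coh <- simulate_connectome_cohort(
    cohort_config(n_subjects = 1000, n_rois = 10, seed = 3)
  )
  sub <- simulate_substance_trajectories(coh, seed = 11)
  for (w in 1:3) {
    sol <- efa_pipeline(sub$tlfb[[w]])
    expect_equal(sol$bartlett$df, ifelse(w == 1, 15, 36))
    expect_lt(sol$bartlett$p, 0.001)
    expect_equal(sol$n_factors, ifelse(w == 1, 2, 3))
    dom <- dominant_factor(sol)
    cig_cb <- dom[c("cig_freq", "cig_amount", "cb_freq", "cb_amount")]
    expect_length(unique(cig_cb), 1)                 # Cig+CB co-load
    expect_false(any(dom[c("alc_freq", "alc_amount")] %in% cig_cb))
  }
})
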