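make_edge_cohort <- function(n = 120, n_edges = 66, r = 0.4, n_signal = 6,
                             seed = 1) {
  set.seed(seed)
  trait <- rnorm(n)
  E <- matrix(rnorm(n * n_edges), n, n_edges)
  pos <- seq_len(n_signal / 2)
  neg <- n_signal / 2 + seq_len(n_signal / 2)
  E[, pos] <- r * trait + sqrt(1 - r^2) * E[, pos]
  E[, neg] <- -r * trait + sqrt(1 - r^2) * E[, neg]
  list(E = E, y = trait, pos = pos, neg = neg)
}

test_that("edge vectorization is the documented bijection", {
  M <- matrix(0, 3, 3)
  M[1, 2] <- M[2, 1] <- 5; M[1, 3] <- M[3, 1] <- 7; M[2, 3] <- M[3, 2] <- 9
  ce <- vectorize_edges(list(M))
  expect_equal(as.vector(ce$edges), c(5, 7, 9))
  expect_equal(ce$edge_index$i, c(1, 1, 2))
  expect_equal(ce$edge_index$j, c(2, 3, 3))
  expect_identical(devectorize_edges(ce$edges[1, ], 3), M)
  # 268-ROI atlas size
  expect_equal(268 * 267 / 2, 35778)
  set.seed(2)
  S <- symmetrize_matrix(matrix(rnorm(100), 10, 10))
  expect_identical(devectorize_edges(vectorize_edges(list(S))$edges[1, ], 10), S)
})

test_that("partial correlations reduce to Pearson without covariates", {
  set.seed(3)
  E <- matrix(rnorm(200), 50, 4)
  y <- rnorm(50)
  st <- edge_partial_correlations(E, y)
  expect_equal(st$r, as.vector(cor(E, y)), tolerance = 1e-12)
  ct <- cor.test(E[, 2], y)
  expect_equal(st$p[2], ct$p.value, tolerance = 1e-10)
})

test_that("partial correlations control covariates and flag degenerate edges", {
  set.seed(4)
  n <- 200
  conf <- rnorm(n)
  y <- conf + rnorm(n, sd = 0.3)
  E <- matrix(rnorm(n * 5), n, 5)
  E[, 1] <- conf + rnorm(n, sd = 0.3)          # confound-driven edge
  E[, 2] <- 0                                   # zero variance
  st_raw <- edge_partial_correlations(E, y)
  st_adj <- edge_partial_correlations(E, y, data.frame(conf = conf))
  expect_lt(abs(st_adj$r[1]), abs(st_raw$r[1]))
  expect_true(st_adj$flagged[2])
  expect_equal(st_adj$r[2], 0); expect_equal(st_adj$p[2], 1)
  expect_error(edge_partial_correlations(E, y, data.frame(y = y)),
               class = "sustattn_invalid_input")
})

test_that("planted edges reach significance with the expected power", {
  hits <- sapply(1:20, function(s) {
    d <- make_edge_cohort(n = 200, r = 0.5, n_signal = 2, seed = 100 + s)
    st <- edge_partial_correlations(d$E, d$y)
    st$p[1] < 0.01
  })
  expect_gte(mean(hits), 0.95)
})

test_that("edge selection splits by sign and is antisymmetric in the phenotype", {
  d <- make_edge_cohort(seed = 5)
  st <- edge_partial_correlations(d$E, d$y)
  m1 <- select_edges(st, 0.01)
  st_neg <- edge_partial_correlations(d$E, -d$y)
  m2 <- select_edges(st_neg, 0.01)
  expect_identical(m1$positive, m2$negative)
  expect_identical(m1$negative, m2$positive)
})

test_that("selection rate on pure noise matches the nominal threshold", {
  set.seed(6)
  E <- matrix(rnorm(100 * 12000), 100, 12000)
  y <- rnorm(100)
  st <- edge_partial_correlations(E, y)
  frac <- (length(select_edges(st, 0.01)$positive) +
             length(select_edges(st, 0.01)$negative)) / ncol(E)
  expect_gt(frac, 0.005); expect_lt(frac, 0.015)
})

test_that("network strength sums masked edges; combined = positive - negative", {
  v <- c(e1 = 0.5, e2 = -0.2, e3 = 1)
  expect_equal(network_strength(v, c(1, 2)), 0.3)
  expect_warning(s0 <- network_strength(v, integer(0)), "empty")
  expect_equal(s0, 0)
  masks <- structure(list(positive = c(1, 3), negative = integer(0),
                          p_thresh = 0.01), class = "edge_masks")
  expect_equal(network_strength(v, masks, "combined"),
               network_strength(v, masks, "positive"))
  # linearity: strength(a*M) = a*strength(M)
  expect_equal(network_strength(3 * v, c(1, 3)), 3 * network_strength(v, c(1, 3)))
})

test_that("linear predictor is exact on noiseless data and recovers slopes", {
  set.seed(7)
  s_tr <- rnorm(60); s_te <- rnorm(20)
  fit <- fit_predict_linear(s_tr, 2 * s_tr + 1, s_te)
  expect_equal(fit$predicted, 2 * s_te + 1, tolerance = 1e-10)
  s <- rnorm(500)
  y <- 0.7 * s + rnorm(500, sd = 0.1)
  fit <- fit_predict_linear(s, y, s)
  expect_lt(abs(fit$coefficients["strength"] - 0.7), 0.05)
  expect_error(fit_predict_linear(rep(1, 60), rnorm(60), s_te),
               class = "sustattn_invalid_input")
})

test_that("cross-validation is leakage-free, deterministic, and honest on nulls", {
  d <- make_edge_cohort(n = 80, seed = 8)
  cv1 <- run_cv(d$E, d$y, scheme = "kfold", k = 5, n_repeats = 2, seed = 99)
  cv2 <- run_cv(d$E, d$y, scheme = "kfold", k = 5, n_repeats = 2, seed = 99)
  expect_identical(cv1$networks, cv2$networks)
  expect_identical(cv1$selection_fraction, cv2$selection_fraction)

  # no leakage: training-fold selection ignores held-out subjects entirely
  set.seed(11)
  folds <- sample(rep(1:5, length.out = 80))
  tr <- folds != 1
  st_full <- edge_partial_correlations(d$E[tr, ], d$y[tr])
  drop_one <- which(!tr)[1]
  keep <- setdiff(seq_len(80), drop_one)
  tr2 <- folds[keep] != 1
  st_drop <- edge_partial_correlations(d$E[keep, ][tr2, ], d$y[keep][tr2])
  expect_identical(select_edges(st_full, 0.01), select_edges(st_drop, 0.01))

  # permuted phenotype yields mean r near zero
  rs <- sapply(1:10, function(s) {
    set.seed(400 + s)
    run_cv(d$E, sample(d$y), k = 5, n_repeats = 1)$networks$combined$r_mean
  })
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("leave-site-out uses one fold per site and validates site size", {
  d <- make_edge_cohort(n = 160, seed = 9)
  covs <- data.frame(site = rep(paste0("s", 1:8), each = 20))
  cv <- run_cv(d$E, d$y, covs, scheme = "leave_site_out")
  expect_equal(cv$config$k, 8)
  expect_equal(cv$config$n_repeats, 1)
  covs_bad <- covs; covs_bad$site[1:159] <- "s1"; covs_bad$site[160] <- "tiny"
  err <- tryCatch(run_cv(d$E, d$y, covs_bad, scheme = "leave_site_out"),
                  error = identity)
  expect_s3_class(err, "sustattn_invalid_input")
  expect_match(conditionMessage(err), "tiny")
})

test_that("consensus masks are monotone in the threshold", {
  d <- make_edge_cohort(n = 100, seed = 10)
  cv <- run_cv(d$E, d$y, k = 5, n_repeats = 10, seed = 3)
  for (pol in c("positive", "negative")) {
    frac <- cv$selection_fraction[[pol]]
    loose <- which(frac >= 0.80)
    strict <- which(frac >= 0.95)
    expect_true(all(strict %in% loose))
  }
})

test_that("permutation p-values follow the counting convention", {
  d <- make_edge_cohort(n = 60, n_edges = 30, r = 0.7, seed = 12)
  pt <- permutation_test(d$E, d$y, k = 5, n_repeats = 1, n_perm = 199,
                         seed = 13)
  # strong signal: observed r beats every null draw
  expect_equal(unname(pt$p["combined"]), 1 / 200)
  expect_warning(
    permutation_test(d$E, d$y, k = 5, n_repeats = 1, n_perm = 50, seed = 1),
    "unstable"
  )
})

test_that("a trained model serializes to JSON and reloads identically", {
  d <- make_edge_cohort(seed = 14)
  m <- cpm_train(d$E, d$y)
  path <- withr::local_tempfile(fileext = ".json")
  write_cpm_model(m, path)
  m2 <- read_cpm_model(path)
  expect_equal(m2$masks$positive, m$masks$positive)
  expect_equal(m2$coefficients$combined, as.list(m$coefficients$combined),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("frozen-model transfer matches in-sample application on the source", {
  d <- make_edge_cohort(n = 100, seed = 15)
  m <- cpm_train(d$E, d$y)
  out <- apply_model_across(m, d$E, d$y, mode = "transfer", n_perm = 99,
                            seed = 2)
  s <- network_strength(d$E, m$masks, "combined")
  pred <- m$coefficients$combined[1] + m$coefficients$combined["strength"] * s
  expect_equal(out$combined$predicted, unname(pred), tolerance = 1e-12)
  expect_error(
    apply_model_across(m, d$E[, 1:10], d$y, mode = "transfer"),
    class = "sustattn_invalid_input"
  )
})

test_that("residualizing a site-confounded strength shrinks the correlation", {
  set.seed(16)
  n <- 160
  site <- rep(1:8, each = 20)
  site_eff <- rnorm(8)[site]
  E <- matrix(rnorm(n * 40), n, 40) + site_eff       # site shifts every edge
  y <- site_eff + rnorm(n, sd = 0.5)                 # phenotype follows site
  m <- cpm_train(E, y, p_thresh = 0.3)
  covs <- data.frame(site = factor(site))
  raw <- apply_model_across(m, E, y, mode = "transfer", n_perm = 99, seed = 3)
  res <- apply_model_across(m, E, y, covariates = covs,
                            mode = "residual_correlation", n_perm = 99,
                            seed = 3)
  expect_lt(abs(res$positive$r), abs(raw$positive$r))
})
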