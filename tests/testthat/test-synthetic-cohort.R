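test_that("SST simulator keeps the SSD staircase on its grid", {
  tr <- simulate_sst_trials(n_go = 200, n_stop = 500, seed = 1)
  st <- tr[tr$trial_type == "stop", ]
  expect_true(all(st$ssd %% 50 == 0))
  expect_true(all(st$ssd >= 250 & st$ssd <= 900))
  expect_true(all(is.na(tr$ssd[tr$trial_type == "go"])))
  expect_error(simulate_sst_trials(mu_go = 100, ssrt = 200),
               class = "sustattn_invalid_input")
})

test_that("simulated ICV matches the generative coefficient of variation", {
  tr <- simulate_sst_trials(n_go = 400, n_stop = 80, mu_go = 500, sd_go = 100,
                            p_omission = 0, p_choice_error = 0, p_late = 0,
                            seed = 2)
  s <- compute_behavioral_summary(tr)
  expect_lt(abs(s$icv - 0.2), 0.02)
})

test_that("cohort generation is a pure function of (config, seed)", {
  cfg <- cohort_config(n_subjects = 50, n_rois = 12, seed = 5)
  a <- simulate_connectome_cohort(cfg)
  b <- simulate_connectome_cohort(cfg)
  expect_identical(a$waves[[2]]$edges$edges, b$waves[[2]]$edges$edges)
  expect_identical(a$waves[[1]]$covariates, b$waves[[1]]$covariates)
  s1 <- simulate_substance_trajectories(a, seed = 9)
  s2 <- simulate_substance_trajectories(b, seed = 9)
  expect_identical(s1$tlfb, s2$tlfb)
})

test_that("wave-1 ICV calibrates to the configured mean and SD", {
  coh <- simulate_connectome_cohort(
    cohort_config(n_subjects = 2000, n_rois = 10, seed = 6)
  )
  icv1 <- coh$waves[[1]]$phenotype
  expect_lt(abs(mean(icv1) - 0.234), 0.02 * 0.234 + 0.002)
  expect_lt(abs(sd(icv1) - 0.038), 0.02 * 0.038 + 0.002)
})

test_that("inter-wave ICV rank stability tracks the configured rho", {
  coh <- simulate_connectome_cohort(
    cohort_config(n_subjects = 1000, n_rois = 10, rank_stability = 0.5,
                  seed = 7)
  )
  icv <- sapply(coh$waves, function(w) w$phenotype)
  expect_lt(abs(cor(icv[, 1], icv[, 2], method = "spearman") - 0.5), 0.05)
  expect_lt(abs(cor(icv[, 2], icv[, 3], method = "spearman") - 0.5), 0.05)
})

test_that("site assignment is balanced and covariates are complete", {
  coh <- simulate_connectome_cohort(
    cohort_config(n_subjects = 201, n_rois = 10, seed = 8)
  )
  tab <- table(coh$waves[[1]]$covariates$site)
  expect_lte(max(tab) - min(tab), 1)
  expect_false(anyNA(coh$waves[[1]]$covariates))
  # wave-1 PDS is mode-centred
  expect_true("pds" %in% names(coh$waves[[1]]$covariates))
  expect_false("pds" %in% names(coh$waves[[2]]$covariates))
})

test_that("planted edges carry the configured effect size", {
  coh <- simulate_connectome_cohort(
    cohort_config(n_subjects = 2000, n_rois = 20, seed = 9)
  )
  gt <- coh$ground_truth
  w1 <- coh$waves[[1]]
  rs_pos <- cor(w1$edges$edges[, gt$planted_positive], w1$phenotype)
  rs_null <- cor(
    w1$edges$edges[, setdiff(seq_len(190), c(gt$planted_positive,
                                             gt$planted_negative))[1:50]],
    w1$phenotype
  )
  expect_lt(abs(mean(rs_pos) - gt$edge_effect_r), 0.04)
  expect_lt(abs(mean(rs_null)), 0.04)
})

test_that("infeasible configurations are rejected", {
  expect_error(cohort_config(n_rois = 5, n_pos_edges = 20),
               class = "sustattn_invalid_input")
  expect_error(cohort_config(icv_sd = c(-1, 1, 1)),
               class = "sustattn_invalid_input")
  expect_error(cohort_config(edge_effect_r = 1.2),
               class = "sustattn_invalid_input")
})

test_that("noise-free edges drive CPM to near-exact recovery", {
  # scaling the planted-edge noise to zero: edges become deterministic in the
  # trait, so full-sample selection finds exactly the planted set
  set.seed(10)
  n <- 100
  trait <- rnorm(n)
  E <- matrix(rnorm(n * 50, sd = 1e-8), n, 50)
  E[, 1:5] <- trait; E[, 6:10] <- -trait
  st <- edge_partial_correlations(E, trait)
  masks <- select_edges(st)
  expect_setequal(masks$positive, 1:5)
  expect_setequal(masks$negative, 6:10)
})

test_that("substance trajectories couple to attention as configured", {
  coh <- simulate_connectome_cohort(
    cohort_config(n_subjects = 1500, n_rois = 10, seed = 11)
  )
  sub <- simulate_substance_trajectories(coh, gamma1 = 0, gamma2 = 0.3,
                                         seed = 12)
  # lagged effect: attention trait at wave 1 predicts the change in Cig+CB
  dx <- sub$factors$cigcb[, 2] - sub$factors$cigcb[, 1]
  fit <- lm(dx ~ sub$factors$cigcb[, 1] + sub$attention[, 1])
  expect_lt(abs(coef(fit)[3] - 0.3), 0.05)
  # TLFB counts are nonnegative integers with exact zeros present
  tl <- as.matrix(sub$tlfb[[2]])
  expect_true(all(tl >= 0))
  expect_true(all(tl == round(tl)))
  expect_gt(mean(tl == 0), 0.05)
})

test_that("end-to-end asymmetry: gamma2 coupling is recovered by the SEM", {
  ok <- sapply(1:5, function(s) {
    coh <- simulate_connectome_cohort(
      cohort_config(n_subjects = 1000, n_rois = 10, seed = 100 + s)
    )
    sub <- simulate_substance_trajectories(coh, gamma1 = 0, gamma2 = 0.12,
                                           seed = 200 + s)
    f <- fit_ml(build_lcs_spec(sub$factors$cigcb, sub$attention),
                n_restarts = 2, seed = 300 + s)
    f$params$gamma2 > f$params$gamma1
  })
  expect_gte(mean(ok), 0.8)
})
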