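# Synthetic cohort generator.
#
# Emulates the statistical structure the pipeline assumes so every stage is
# testable without restricted data: a three-wave cohort (ages 14/19/23, 8
# acquisition sites) with a latent sustained-attention trait that evolves
# with configurable inter-wave rank stability; ICV calibrated per wave to the
# observed cohort means/SDs; planted positive/negative predictive edge
# networks; substance-use factors following bivariate latent change score
# dynamics with configurable cross-lagged couplings; and rounded-lognormal
# TLFB consumption counts with a cigarette+cannabis / alcohol / drugs
# loading structure. Every generator is a pure function of (config, seed).

rtruncnorm_pos <- function(n, mean, sd) {
  u <- stats::runif(n, stats::pnorm(0, mean, sd), 1)
  stats::qnorm(u, mean, sd)
}

#' Simulate stop-signal-task trials under the staircase race model
#'
#' Independent race: the Go process finishes at a truncated-normal latency;
#' a stop trial succeeds iff the Go finish time exceeds SSD + SSRT. The SSD
#' staircase steps +50 ms after a successful stop and -50 ms after a failed
#' stop, clamped to 250-900 ms, targeting 50% successful inhibition. Go
#' trials receive omissions, wrong-side responses and late responses at the
#' configured rates; 3-7 Go trials separate successive Stop trials.
#'
#' @param n_go,n_stop trial counts (400/80 at wave 1; 300/60 later).
#' @param mu_go,sd_go Go finish-time distribution (ms).
#' @param ssrt generative stop-signal reaction time (ms).
#' @param ssd_start initial SSD (ms, on the 50 ms grid).
#' @param p_omission,p_choice_error,p_late Go-trial error rates.
#' @param seed RNG seed.
#' @return trial data.frame in [validate_trials()] layout.
#' @export
simulate_sst_trials <- function(n_go = 400, n_stop = 80,
                                mu_go = 500, sd_go = 100, ssrt = 200,
                                ssd_start = 300,
                                p_omission = 0.04, p_choice_error = 0.05,
                                p_late = 0.02, seed = NULL) {
  if (!(mu_go > ssrt && ssrt > 0)) {
    stop(invalid_input("need mean Go RT > SSRT > 0"))
  }
  if (!is.null(seed)) set.seed(seed)
  # interleave: 3-7 go trials between successive stop trials
  types <- character(0)
  go_left <- n_go
  for (s in seq_len(n_stop)) {
    gap <- min(sample(3:7, 1), go_left)
    types <- c(types, rep("go", gap), "stop")
    go_left <- go_left - gap
  }
  if (go_left > 0) types <- c(types, rep("go", go_left))
  n <- length(types)

  ssd <- rep(NA_real_, n)
  response <- character(n)
  rt <- rep(NA_real_, n)
  late <- rep(FALSE, n)
  correct_side <- sample(c("left", "right"), n, replace = TRUE)
  other <- ifelse(correct_side == "left", "right", "left")

  cur_ssd <- ssd_start
  for (i in seq_len(n)) {
    if (types[i] == "go") {
      u <- stats::runif(1)
      if (u < p_omission) {
        response[i] <- "none"
      } else {
        rt[i] <- rtruncnorm_pos(1, mu_go, sd_go)
        if (u < p_omission + p_choice_error) {
          response[i] <- other[i]
        } else {
          response[i] <- correct_side[i]
          late[i] <- stats::runif(1) < p_late
        }
      }
    } else {
      ssd[i] <- cur_ssd
      finish <- rtruncnorm_pos(1, mu_go, sd_go)
      if (finish > cur_ssd + ssrt) {       # stop process wins
        response[i] <- "none"
        cur_ssd <- min(cur_ssd + 50, 900)
      } else {
        response[i] <- correct_side[i]
        rt[i] <- finish
        cur_ssd <- max(cur_ssd - 50, 250)
      }
    }
  }
  data.frame(
    trial_index = seq_len(n), trial_type = types,
    onset = (seq_len(n) - 1) * 2.5, ssd = ssd,
    response = response, correct_side = correct_side,
    rt = rt, late_flag = late
  )
}

#' Generate a stop-signal-task event table for an fMRI run
#'
#' @param n_time,tr run length (samples) and repetition time (s).
#' @param iti_range inter-trial-interval range (s).
#' @param p_go,p_stop_success condition probabilities (failed stops take the
#'   remainder).
#' @param seed RNG seed.
#' @export
simulate_task_events <- function(n_time, tr, iti_range = c(3, 5),
                                 p_go = 0.7, p_stop_success = 0.15,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t_end <- n_time * tr - 16
  onsets <- c()
  t <- 8
  while (t < t_end) {
    onsets <- c(onsets, t)
    t <- t + stats::runif(1, iti_range[1], iti_range[2])
  }
  conds <- sample(c("go", "stop_success", "stop_fail"), length(onsets),
                  replace = TRUE,
                  prob = c(p_go, p_stop_success, 1 - p_go - p_stop_success))
  data.frame(onset = onsets, duration = 1, condition = conds)
}

# Smooth neural base signal: low-frequency cosine mixture with unit SD.
# The default band (frequencies up to ~1/3 of the TR Nyquist) is broad enough
# that chance correlations between independent ROIs stay small, yet lies
# within the band the HRF transmits.
smooth_neural <- function(n_time, n_basis = NULL) {
  if (is.null(n_basis)) n_basis <- max(4L, floor(n_time / 3))
  B <- dct_basis(n_time, n_basis)
  w <- stats::rnorm(n_basis) / seq_len(n_basis)^0.5
  z <- drop(B %*% w)
  z / stats::sd(z)
}

# Project neural signals onto the subspace the HRF convolution operator can
# transmit within the run (directions with non-negligible singular values).
# Components outside it -- chiefly the last few samples, whose haemodynamic
# response falls beyond the acquisition -- are unobservable in BOLD, so a
# generative neural signal with energy there could never be recovered by any
# deconvolution.
recoverable_neural <- function(Z, n_time, kernel_tr, rel_tol = 1e-3) {
  op <- deconv_operator(n_time, kernel_tr)
  keep <- op$d > rel_tol * max(op$d)
  W <- crossprod(op$B, Z)
  A <- crossprod(op$v, W)
  A[!keep, ] <- 0
  op$B %*% (op$v %*% A)
}

#' Simulate ROI time series with planted condition-gated couplings
#'
#' Forward model of the gPPI generative structure: each ROI has a smooth
#' neural base signal convolved with the HRF; a planted coupling (i, j,
#' condition, value) adds value * HRF*(z_j * boxcar_condition) to seed ROI i;
#' 9 base nuisance signals (6 motion, 3 tissue means) load weakly on every
#' ROI; white noise is added on top.
#'
#' @param n_rois number of ROIs.
#' @param n_time,tr run dimensions.
#' @param events event table (generated internally when NULL).
#' @param couplings data.frame(i, j, condition, value) or NULL.
#' @param noise_sd white-noise SD (0 for exact-recovery checks).
#' @param nuisance_load loading of the nuisance signals onto the BOLD data.
#' @param hrf optional `hrf_model`.
#' @param seed RNG seed.
#' @return list with `ts` ([roi_timeseries()]), `events`, `confounds` (9
#'   base columns), `neural` (time-by-ROI base signals), and the ground-truth
#'   `couplings`.
#' @export
simulate_ppi_timeseries <- function(n_rois, n_time = 400, tr = 2.2,
                                    events = NULL, couplings = NULL,
                                    noise_sd = 0.5, nuisance_load = 0.1,
                                    hrf = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(hrf)) hrf <- canonical_hrf(tr)
  if (is.null(events)) events <- simulate_task_events(n_time, tr)
  k_tr <- hrf_kernel_tr(hrf)
  times <- (seq_len(n_time) - 1L) * tr

  Z <- sapply(seq_len(n_rois), function(i) smooth_neural(n_time))
  Z <- recoverable_neural(Z, n_time, k_tr)
  Z <- scale(Z, center = FALSE, scale = apply(Z, 2, stats::sd))
  Y <- apply(Z, 2, convolve_causal, k = k_tr)

  if (!is.null(couplings) && nrow(couplings) > 0) {
    if (any(!is.finite(couplings$value))) stop(invalid_input("non-finite coupling"))
    for (r in seq_len(nrow(couplings))) {
      psy <- condition_boxcar(events, couplings$condition[r], times)
      Y[, couplings$i[r]] <- Y[, couplings$i[r]] +
        couplings$value[r] * convolve_causal(Z[, couplings$j[r]] * psy, k_tr)
    }
  }

  motion <- sapply(1:6, function(i) {
    drop(stats::filter(stats::rnorm(n_time, sd = 0.05), 0.95, "recursive"))
  })
  tissue <- sapply(1:3, function(i) smooth_neural(n_time) * 0.5)
  confounds <- cbind(motion, tissue)
  colnames(confounds) <- c(paste0("trans_", c("x", "y", "z")),
                           paste0("rot_", c("x", "y", "z")),
                           c("wm", "csf", "gm"))
  loads <- matrix(stats::rnorm(9 * n_rois, sd = nuisance_load), 9, n_rois)
  Y <- Y + confounds %*% loads
  if (noise_sd > 0) Y <- Y + matrix(stats::rnorm(n_time * n_rois, sd = noise_sd),
                                    n_time, n_rois)
  list(
    ts = roi_timeseries(Y, tr = tr),
    events = events,
    confounds = as.data.frame(confounds),
    neural = Z,
    couplings = couplings
  )
}

#' Simulate a single seed/target BOLD pair from the gPPI regression model
#'
#' Forward model of the pair GLM itself: the target is its (band-limited)
#' neural signal convolved with the HRF plus white noise; the seed is built
#' from the regression equation -- physiological coupling times the noiseless
#' target BOLD, psychological task effects, the planted PPI effect
#' (HRF-convolved condition-gated neural signal), plus white noise. With
#' `noise_sd = 0` the seed lies exactly in the span of the fitted design, so
#' the planted PPI coefficient is recovered to numerical precision.
#'
#' @param ppi_value planted PPI coefficient for the condition of interest.
#' @param n_time,tr run dimensions.
#' @param model condition model; the planted PPI term is the go condition for
#'   "go_trials" and the successful-stop condition for "successful_stop".
#' @param physio physiological coupling coefficient.
#' @param psycho_effect amplitude of each task-condition effect on the seed.
#' @param noise_sd SD of the GLM residual: white observation noise on the
#'   seed (modeled) series.
#' @param target_noise_sd white-noise SD on the target series. Regressor-side
#'   noise induces the errors-in-variables attenuation/inflation that affects
#'   every deconvolution-based PPI estimate; default 0 so that recovery
#'   checks isolate the estimator's behaviour under its own model.
#' @param events optional event table; generated when NULL.
#' @param hrf optional `hrf_model`.
#' @param seed RNG seed.
#' @return list with `seed`, `target`, `events`, `confounds`, and the
#'   generative values.
#' @export
simulate_gppi_pair <- function(ppi_value = 0.8, n_time = 300, tr = 2.2,
                               model = c("go_trials", "successful_stop"),
                               physio = 0.5, psycho_effect = 0.3,
                               noise_sd = 0, target_noise_sd = 0,
                               events = NULL, hrf = NULL, seed = NULL) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(hrf)) hrf <- canonical_hrf(tr)
  if (is.null(events)) events <- simulate_task_events(n_time, tr)
  k_tr <- hrf_kernel_tr(hrf)
  times <- (seq_len(n_time) - 1L) * tr

  z_t <- drop(recoverable_neural(cbind(smooth_neural(n_time)), n_time, k_tr))
  target_clean <- convolve_causal(z_t, k_tr)
  # unit-variance BOLD (grand-mean-scaled units); neural scaled consistently
  z_t <- z_t / stats::sd(target_clean)
  target_clean <- target_clean / stats::sd(target_clean)

  conds <- if (model == "go_trials") c("stop_success", "stop_fail", "go") else
    c("stop_success", "stop_fail")
  cond_int <- if (model == "go_trials") "go" else "stop_success"
  task <- task_regressors(events, conds, n_time, tr, hrf)
  seed_sig <- physio * target_clean + drop(task %*% rep(psycho_effect, length(conds)))
  psy_int <- condition_boxcar(events, cond_int, times)
  seed_sig <- seed_sig + ppi_value * convolve_causal(z_t * psy_int, k_tr)
  target <- target_clean + stats::rnorm(n_time, sd = target_noise_sd)
  seed_bold <- seed_sig + stats::rnorm(n_time, sd = noise_sd)
  confounds <- matrix(stats::rnorm(n_time * 9, sd = 0.05), n_time, 9)
  colnames(confounds) <- c(paste0("trans_", c("x", "y", "z")),
                           paste0("rot_", c("x", "y", "z")),
                           c("wm", "csf", "gm"))
  list(
    seed = seed_bold, target = target, events = events,
    confounds = as.data.frame(confounds),
    neural = z_t, target_clean = target_clean,
    truth = list(ppi_value = ppi_value, physio = physio,
                 psycho_effect = psycho_effect, noise_sd = noise_sd,
                 target_noise_sd = target_noise_sd, model = model)
  )
}

#' Cohort configuration
#'
#' Defaults are the desk-scale study conditions: 200 subjects, 60 ROIs, 20
#' positive + 20 negative planted edges with effect r = 0.32, inter-wave
#' trait stability 0.5, ICV calibration (0.234, 0.038), (0.224, 0.051),
#' (0.217, 0.052) across the three waves, and 8 balanced acquisition sites.
#'
#' @param n_subjects,n_rois cohort and atlas size.
#' @param n_sites acquisition sites (balanced assignment).
#' @param n_pos_edges,n_neg_edges planted predictive edges per polarity.
#' @param edge_effect_r correlation of a planted edge with the attention
#'   trait (positive edges +, negative edges -).
#' @param rank_stability inter-wave autocorrelation of the attention trait.
#' @param icv_mean,icv_sd per-wave ICV calibration targets.
#' @param site_effect_sd SD of per-site additive edge offsets.
#' @param gamma1,gamma2 substance <-> attention cross-lagged couplings used
#'   by [simulate_substance_trajectories()].
#' @param seed RNG seed; together with the config it fully determines every
#'   generated dataset.
#' @export
cohort_config <- function(n_subjects = 200, n_rois = 60, n_sites = 8,
                          n_pos_edges = 20, n_neg_edges = 20,
                          edge_effect_r = 0.32, rank_stability = 0.5,
                          icv_mean = c(0.234, 0.224, 0.217),
                          icv_sd = c(0.038, 0.051, 0.052),
                          site_effect_sd = 0.1,
                          gamma1 = 0, gamma2 = 0.12, seed = 1L) {
  n_edges <- n_rois * (n_rois - 1) / 2
  if (n_pos_edges + n_neg_edges > n_edges) {
    stop(invalid_input("more planted edges than the atlas has edges"))
  }
  if (any(icv_sd <= 0)) stop(invalid_input("infeasible ICV calibration (sd <= 0)"))
  if (abs(edge_effect_r) >= 1) stop(invalid_input("edge effect must be |r| < 1"))
  structure(
    list(
      n_subjects = n_subjects, n_rois = n_rois, n_sites = n_sites,
      n_waves = 3L, n_pos_edges = n_pos_edges, n_neg_edges = n_neg_edges,
      edge_effect_r = edge_effect_r, rank_stability = rank_stability,
      icv_mean = icv_mean, icv_sd = icv_sd, site_effect_sd = site_effect_sd,
      gamma1 = gamma1, gamma2 = gamma2, seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' Simulate a three-wave connectome cohort
#'
#' A latent attention trait (unit variance) evolves across waves with the
#' configured autocorrelation; ICV at each wave is an affine transform of the
#' trait calibrated to the per-wave (mean, SD) targets, so inter-wave ICV
#' rank stability equals the trait stability. Planted positive (negative)
#' edges equal +r (-r) times the trait plus sqrt(1 - r^2) noise; null edges
#' are unit noise; per-site offsets are added to every edge. Covariates (age,
#' sex, site, mean FD, wave-1 mode-centred PDS) are drawn from realistic
#' distributions and are independent of the trait.
#'
#' @param config a [cohort_config()].
#' @return object of class `synthetic_cohort`: `waves` (list of per-wave
#'   edges / phenotype / covariates), and `ground_truth` (planted masks,
#'   traits, per-wave predictable ceiling r for the three networks).
#' @export
simulate_connectome_cohort <- function(config = cohort_config()) {
  set.seed(config$seed)
  n <- config$n_subjects
  n_edges <- config$n_rois * (config$n_rois - 1) / 2
  rho <- config$rank_stability

  traits <- matrix(NA_real_, n, 3)
  traits[, 1] <- stats::rnorm(n)
  for (w in 2:3) {
    traits[, w] <- rho * traits[, w - 1] + sqrt(1 - rho^2) * stats::rnorm(n)
  }

  all_idx <- sample(n_edges, config$n_pos_edges + config$n_neg_edges)
  pos_idx <- sort(all_idx[seq_len(config$n_pos_edges)])
  neg_idx <- sort(all_idx[config$n_pos_edges + seq_len(config$n_neg_edges)])

  site <- factor(sample(rep_len(seq_len(config$n_sites), n)))
  site_off <- matrix(stats::rnorm(config$n_sites * n_edges,
                                  sd = config$site_effect_sd),
                     config$n_sites, n_edges)
  sex <- sample(c(0L, 1L), n, replace = TRUE)
  pds <- sample(1:5, n, replace = TRUE, prob = c(0.05, 0.2, 0.4, 0.25, 0.1))
  pds_mode <- as.integer(names(which.max(table(pds))))
  age_mean <- c(14.4, 19.0, 22.6); age_sd <- c(0.4, 0.7, 0.7)
  fd_meanlog <- log(c(0.22, 0.16, 0.16))

  r <- config$edge_effect_r
  waves <- vector("list", 3)
  ceiling_r <- matrix(NA_real_, 3, 3,
                      dimnames = list(NULL, c("positive", "negative", "combined")))
  for (w in 1:3) {
    E <- matrix(stats::rnorm(n * n_edges), n, n_edges)
    E[, pos_idx] <- r * traits[, w] + sqrt(1 - r^2) * E[, pos_idx]
    E[, neg_idx] <- -r * traits[, w] + sqrt(1 - r^2) * E[, neg_idx]
    icv <- config$icv_mean[w] + config$icv_sd[w] * traits[, w]
    s_pos <- rowSums(E[, pos_idx, drop = FALSE])
    s_neg <- rowSums(E[, neg_idx, drop = FALSE])
    ceiling_r[w, ] <- c(stats::cor(s_pos, icv), stats::cor(-s_neg, icv),
                        stats::cor(s_pos - s_neg, icv))
    E <- E + site_off[as.integer(site), ]
    cov_df <- data.frame(
      age = stats::rnorm(n, age_mean[w], age_sd[w]),
      sex = sex,
      mean_fd = pmin(stats::rlnorm(n, fd_meanlog[w], 0.6), 1.5),
      site = site
    )
    if (w == 1L) cov_df$pds <- pds - pds_mode
    edges <- structure(
      list(
        edges = E,
        edge_index = {
          ut <- which(upper.tri(matrix(0, config$n_rois, config$n_rois)),
                      arr.ind = TRUE)
          data.frame(edge = seq_len(n_edges), i = ut[, 1], j = ut[, 2])
        },
        n_roi = config$n_rois,
        subject_ids = paste0("sub", seq_len(n)), wave = w
      ),
      class = "cohort_edges"
    )
    waves[[w]] <- list(edges = edges, phenotype = icv, covariates = cov_df)
  }

  structure(
    list(
      waves = waves,
      ground_truth = list(
        planted_positive = pos_idx, planted_negative = neg_idx,
        traits = traits, edge_effect_r = r, ceiling_r = ceiling_r
      ),
      config = config
    ),
    class = "synthetic_cohort"
  )
}

#' Simulate substance-use trajectories and TLFB counts for a cohort
#'
#' Latent substance factors follow the bivariate latent change score
#' equations coupled to the cohort's attention trait: the Cig+CB factor
#' receives the `gamma2` lagged effect of attention; a non-zero `gamma1`
#' (substance -> attention) regenerates the attention series with that
#' feedback (returned as `attention`; the cohort's connectomes refer to the
#' original trait, so non-zero gamma1 is intended for behavioural analyses).
#' Alcohol and (waves 2-3) drug factors are uncoupled. Observed TLFB 30-day
#' counts are rounded lognormal transforms of the factors: 2 alcohol + 2
#' cigarette + 2 cannabis items at wave 1, plus cocaine / ecstasy / ketamine
#' at waves 2-3; cigarette and cannabis items load on the shared Cig+CB
#' factor.
#'
#' @param cohort a [simulate_connectome_cohort()] result.
#' @param gamma1,gamma2 cross-lagged couplings (defaults from the cohort
#'   config).
#' @param baseline_cor wave-1 correlation between the Cig+CB factor and the
#'   attention trait (0 gives a fully null substance-attention coupling).
#' @param beta self-feedback of the change scores.
#' @param psi change residual variance.
#' @param loading,item_noise_sd lognormal item model parameters.
#' @param seed RNG seed.
#' @return list with `tlfb` (per-wave count data.frames), `factors` (true
#'   per-wave factor scores), and `attention` (the attention series used).
#' @export
simulate_substance_trajectories <- function(cohort,
                                            gamma1 = cohort$config$gamma1,
                                            gamma2 = cohort$config$gamma2,
                                            baseline_cor = 0.3,
                                            beta = -0.2, psi = 0.25,
                                            loading = 0.9,
                                            item_noise_sd = 0.45,
                                            seed = cohort$config$seed + 1L) {
  set.seed(seed)
  y <- cohort$ground_truth$traits
  n <- nrow(y)
  rho <- cohort$config$rank_stability

  x <- matrix(NA_real_, n, 3)                   # Cig+CB factor
  x[, 1] <- baseline_cor * y[, 1] + sqrt(1 - baseline_cor^2) * stats::rnorm(n)
  regen_y <- gamma1 != 0
  if (regen_y) {
    y2 <- y
    for (t in 1:2) {
      dy <- (rho - 1) * y2[, t] + gamma1 * x[, t] +
        sqrt(1 - rho^2) * stats::rnorm(n)
      y2[, t + 1] <- y2[, t] + dy
      dx <- beta * x[, t] + gamma2 * y2[, t] + sqrt(psi) * stats::rnorm(n)
      x[, t + 1] <- x[, t] + dx
    }
    y <- y2
  } else {
    for (t in 1:2) {
      dx <- beta * x[, t] + gamma2 * y[, t] + sqrt(psi) * stats::rnorm(n)
      x[, t + 1] <- x[, t] + dx
    }
  }

  # alcohol and drug factors correlate moderately with Cig+CB (substance use
  # co-occurs); without the cross-correlation, doublet/triplet item blocks
  # would fail the per-item KMO >= 0.5 retention rule
  cross <- 0.45
  alc <- matrix(NA_real_, n, 3)
  alc[, 1] <- cross * x[, 1] + sqrt(1 - cross^2) * stats::rnorm(n)
  for (t in 1:2) {
    alc[, t + 1] <- alc[, t] + beta * alc[, t] + sqrt(psi) * stats::rnorm(n)
  }
  drugs <- matrix(NA_real_, n, 3)
  eta2 <- stats::rnorm(n)
  eta3 <- 0.5 * eta2 + sqrt(0.75) * stats::rnorm(n)
  drugs[, 2] <- cross * scale(x[, 2])[, 1] + sqrt(1 - cross^2) * eta2
  drugs[, 3] <- cross * scale(x[, 3])[, 1] + sqrt(1 - cross^2) * eta3

  make_item <- function(f, intercept) {
    pmax(round(exp(intercept + loading * f +
                     item_noise_sd * stats::rnorm(length(f)))), 0)
  }
  tlfb <- vector("list", 3)
  for (w in 1:3) {
    tab <- data.frame(
      alc_freq = make_item(alc[, w], 1.2),
      alc_amount = make_item(alc[, w], 1.0),
      cig_freq = make_item(x[, w], 0.6),
      cig_amount = make_item(x[, w], 0.5),
      cb_freq = make_item(x[, w], 0.3),
      cb_amount = make_item(x[, w], 0.2)
    )
    if (w >= 2) {
      tab$cocaine <- make_item(drugs[, w], -0.8)
      tab$ecstasy <- make_item(drugs[, w], -0.9)
      tab$ketamine <- make_item(drugs[, w], -1.0)
    }
    tlfb[[w]] <- tab
  }
  list(
    tlfb = tlfb,
    factors = list(cigcb = x, alcohol = alc, drugs = drugs),
    attention = y,
    params = list(gamma1 = gamma1, gamma2 = gamma2, beta = beta, psi = psi,
                  loading = loading, item_noise_sd = item_noise_sd)
  )
}
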