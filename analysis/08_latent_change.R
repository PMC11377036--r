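#!/usr/bin/env Rscript
# Bivariate latent change score battery: 2 substance factors (Cig+CB,
# alcohol) x 5 attention measures (ICV + wave-1-model network strengths for
# both condition models' stand-ins), with FDR over the 20 cross-lagged
# effects, mirroring the Table-2 layout.

suppressPackageStartupMessages(library(sustattn))
stopifnot(file.exists("scratch/cohort.rds"))
obj <- readRDS("scratch/cohort.rds")
cohort <- obj$cohort; substance <- obj$substance

m1 <- cpm_train(cohort$waves[[1]]$edges, cohort$waves[[1]]$phenotype,
                cohort$waves[[1]]$covariates)
s_pos <- sapply(cohort$waves, function(w)
  network_strength(w$edges, m1$masks, "positive"))
s_neg <- sapply(cohort$waves, function(w)
  network_strength(w$edges, m1$masks, "negative"))
icv <- sapply(cohort$waves, function(w) w$phenotype)

# the two condition models share planted masks in this cohort, so the
# stop-model strengths are represented by noisier copies of the same signal
set.seed(3)
n <- nrow(icv)
attention <- list(
  icv = icv,
  go_positive = s_pos,
  go_negative = s_neg,
  stop_positive = s_pos + matrix(rnorm(n * 3, sd = sd(s_pos)), n, 3),
  stop_negative = s_neg + matrix(rnorm(n * 3, sd = sd(s_neg)), n, 3)
)
covs <- lapply(cohort$waves, function(w)
  w$covariates[, c("age", "sex", "site")])

battery <- run_battery(
  substance = list(cigcb = substance$factors$cigcb,
                   alcohol = substance$factors$alcohol),
  attention = attention, covariates = covs, seed = 8
)
fits <- attr(battery, "fits")
fi <- t(sapply(fits, function(f) {
  if (inherits(f, "error")) return(c(cfi = NA, rmsea = NA, srmr = NA))
  fit_indices(f)
}))
out <- cbind(battery, round(fi, 3))
write.csv(out, "results/lcs_battery.csv", row.names = FALSE)

cat(sprintf("%d models fitted; %d converged\n", nrow(battery),
            sum(battery$converged)))
cat("Cross-lagged effects (standardized), FDR q < 0.05:\n")
print(out[, c("attention", "substance", "gamma1_std", "gamma1_p",
              "gamma1_fdr_significant", "gamma2_std", "gamma2_p",
              "gamma2_fdr_significant")],
      row.names = FALSE, digits = 2)
cat("\ngamma2 rows flag the planted direction: attention at one wave\n")
cat("predicts the change in Cig+CB use, not the reverse (gamma1).\n")
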