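#!/usr/bin/env Rscript
# Residualized Spearman association grids between attention measures (ICV,
# network strengths) and substance-use factors across all wave pairs, with
# per-grid FDR control, plus quintile trajectory summaries of TLFB counts by
# baseline attention.

suppressPackageStartupMessages(library(sustattn))
stopifnot(file.exists("scratch/cohort.rds"))
obj <- readRDS("scratch/cohort.rds")
cohort <- obj$cohort; substance <- obj$substance

icv <- sapply(cohort$waves, function(w) w$phenotype)
covs <- lapply(cohort$waves, function(w) w$covariates)

# network strengths per wave from a full-sample wave-1 model (frozen masks)
m1 <- cpm_train(cohort$waves[[1]]$edges, cohort$waves[[1]]$phenotype,
                cohort$waves[[1]]$covariates)
strength_pos <- sapply(cohort$waves, function(w)
  network_strength(w$edges, m1$masks, "positive"))
strength_neg <- sapply(cohort$waves, function(w)
  network_strength(w$edges, m1$masks, "negative"))

measures <- list(icv = icv, positive_network = strength_pos,
                 negative_network = strength_neg)
factors <- list(cigcb = substance$factors$cigcb,
                alcohol = substance$factors$alcohol)

grids <- list()
for (mn in names(measures)) for (fn in names(factors)) {
  grids[[paste(mn, fn)]] <- cross_wave_association_grid(
    measures[[mn]], factors[[fn]], covariates = covs,
    measure_label = mn, factor_label = fn
  )
}
grid_tab <- do.call(rbind, grids)
rownames(grid_tab) <- NULL
write.csv(grid_tab, "results/association_grid.csv", row.names = FALSE)
sig <- grid_tab[grid_tab$significant, ]
cat(sprintf("%d / %d grid cells FDR-significant (q < 0.05)\n",
            nrow(sig), nrow(grid_tab)))
print(sig[, c("measure", "factor", "wave_x", "wave_y", "rho", "p_adjusted")],
      row.names = FALSE, digits = 2)

# quintile trajectories of cigarette use by baseline attention
cig <- sapply(1:3, function(w) substance$tlfb[[w]]$cig_freq)
traj <- rbind(
  cbind(measure = "icv",
        quintile_trajectories(icv[, 1], cig, higher_is_low_attention = TRUE)),
  cbind(measure = "negative_network",
        quintile_trajectories(strength_neg[, 1], cig,
                              higher_is_low_attention = FALSE))
)
write.csv(traj, "results/quintile_trajectories.csv", row.names = FALSE)
cat("\nCigarette use by baseline-attention quintile (means per wave):\n")
print(traj[, c("measure", "attention", "wave", "mean", "n")],
      row.names = FALSE, digits = 3)
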