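#!/usr/bin/env Rscript
# Stop-signal-task behaviour: simulate per-subject trial tables for a small
# demonstration sample, summarise the Table-1-style metrics (ICV, SSRT,
# error rates), and apply the inclusion rule (>20% Go errors or mean
# FD > 0.5 mm excluded).

suppressPackageStartupMessages(library(sustattn))
dir.create("results", showWarnings = FALSE)

set.seed(2)
n_subj <- 60
rows <- lapply(seq_len(n_subj), function(i) {
  mu <- rnorm(1, 466.6, 60)                 # between-subject Go RT spread
  sdv <- rnorm(1, 0.234, 0.038) * mu        # per-subject ICV target
  trials <- simulate_sst_trials(n_go = 400, n_stop = 80, mu_go = mu,
                                sd_go = max(sdv, 20), ssrt = 217,
                                seed = 100 + i)
  s <- compute_behavioral_summary(trials)
  ssrt <- compute_ssrt(trials, "integration")
  mean_fd <- rlnorm(1, log(0.22), 0.6)
  excl <- apply_exclusion(s, mean_fd)
  cbind(behavioral_summary_table(list(s)),
        ssrt_integration = ssrt$ssrt, mean_fd = mean_fd,
        included = excl$include,
        reasons = paste(excl$reasons, collapse = ";"))
})
tab <- do.call(rbind, rows)
tab$subject <- sprintf("sub%03d", seq_len(n_subj))
write.csv(tab, "results/behavioral_summary.csv", row.names = FALSE)

cat(sprintf("Simulated %d subjects; %d retained after exclusion\n",
            n_subj, sum(tab$included)))
cat(sprintf("ICV %.3f +/- %.3f | Go RT %.0f +/- %.0f ms | SSRT %.0f ms\n",
            mean(tab$icv), sd(tab$icv), mean(tab$mean_go_rt),
            sd(tab$mean_go_rt), mean(tab$ssrt_integration)))
cat(sprintf("pCommission %.1f%%\n", mean(tab$p_commission)))
cat("(the staircase targets 50% but overshoots when a subject's equilibrium\n")
cat(" SSD falls at or below the 250 ms floor, as for fast responders here)\n")
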