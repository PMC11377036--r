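# Builders for small in-code fixtures shared across test files.

make_go_trials <- function(rts, response = "left", correct_side = "left",
                           late = FALSE) {
  data.frame(
    trial_type = "go",
    response = rep_len(response, length(rts)),
    correct_side = rep_len(correct_side, length(rts)),
    rt = rts,
    late_flag = rep_len(late, length(rts))
  )
}

make_stop_trials <- function(n, ssd = 300, responded = rep(FALSE, n),
                             rt = 450) {
  data.frame(
    trial_type = "stop",
    response = ifelse(responded, "left", "none"),
    correct_side = "left",
    rt = ifelse(responded, rt, NA_real_),
    ssd = ssd,
    late_flag = FALSE
  )
}

# trial table with a controlled commission rate and constant Go RT
make_sst_fixture <- function(go_rt = 500, n_go = 20, n_stop = 10,
                             n_commission = 5, ssd = 300) {
  go <- make_go_trials(rep(go_rt, n_go))
  go$ssd <- NA_real_
  st <- make_stop_trials(n_stop, ssd = ssd,
                         responded = seq_len(n_stop) <= n_commission)
  rbind(go, st)
}

# brute-force Benjamini-Hochberg step-up, written independently of bh_fdr
brute_force_bh <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- 0
  for (i in seq_len(m)) if (ps[i] <= i / m * q) k <- i
  reject <- logical(m)
  if (k > 0) reject[o[seq_len(k)]] <- TRUE
  reject
}

# varimax criterion (sum of column variances of squared loadings)
varimax_criterion <- function(L) {
  sq <- L^2
  sum(apply(sq, 2, function(col) mean(col^2) - mean(col)^2))
}
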