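#!/usr/bin/env Rscript
# Stage 4: adaptive contrast-sensitivity estimation.
#
# Runs the Psi method (45 trials per frequency, six frequencies, 270 trials
# per session) on simulated 2AFC observers with truncated log-parabola CSFs
# and summarizes each session as AULCSF and cut-off SF.
# Writes results/csf_results.csv.

library(myoretina)

seed <- 1
n_obs <- 3
rows <- do.call(rbind, lapply(seq_len(n_obs), function(e) {
  # vary the observer slightly so the three sessions are not replicates
  obs <- gen_observer(observer_spec(peak_gain = c(60, 45, 80)[e],
                                    seed = seed + 200 + e))
  res <- run_session(obs, n_trials = 45, seed = seed + 200 + e)
  true_aulcsf <- aulcsf(obs$log_sens_true, obs$frequencies)
  data.frame(observer = e, frequency_cpd = res$frequencies,
             threshold_true = obs$thresholds,
             threshold_est = res$thresholds,
             log_sens_est = res$log_sensitivities,
             aulcsf_true = true_aulcsf, aulcsf_est = res$aulcsf,
             cutoff_est_log10cpd = as.numeric(res$cutoff_sf))
}))
dir.create("results", showWarnings = FALSE)
write.csv(rows, "results/csf_results.csv", row.names = FALSE)

per_obs <- unique(rows[, c("observer", "aulcsf_true", "aulcsf_est",
                           "cutoff_est_log10cpd")])
message(sprintf("%d sessions of 270 trials each", n_obs))
message(sprintf("AULCSF true vs estimated: %s",
                paste(sprintf("%.2f/%.2f", per_obs$aulcsf_true,
                              per_obs$aulcsf_est), collapse = ", ")))
message(sprintf("cut-off SF estimates: %s log10 cpd",
                paste(round(per_obs$cutoff_est_log10cpd, 2), collapse = ", ")))
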