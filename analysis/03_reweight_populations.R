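#!/usr/bin/env Rscript
# MaxD-normalize each state's uptake, filter peptides, reweight the
# 50:50 OF/IF candidate ensemble to each target with a gamma scan
# under the ~5 kJ/mol apparent-work budget, and quantify the
# fractional conformational populations with subsampling uncertainty
# (n = 3). Requires 01_simulate_data.R.

suppressPackageStartupMessages(library(hdxensemble))

features <- read_features_csv("results/candidate_features.csv")
rates <- load_rates_csv("results/intrinsic_rates.csv")
maxd <- read_uptake_csv("results/uptake_maxd.csv")
labels <- sub("_.*$", "", unique(features$frame_id))
span <- c(1, max(peptides_of(maxd)$end))

pops <- list()
for (state in c("WT", "mutant")) {
  raw <- read_uptake_csv(sprintf("results/uptake_raw_%s.csv", state))
  target <- suppressMessages(filter_peptides(normalize_to_maxd(raw, maxd), span))
  scan <- suppressWarnings(
    gamma_scan(features, rates, beta_params(), target, state = labels))
  write_weights(scan, sprintf("results/weights_%s.csv", state))
  write_scan_trace(scan, sprintf("results/gamma_scan_%s.csv", state))

  pop <- populations(scan$weights, labels)
  sub <- suppressWarnings(subsample_uncertainty(
    features, labels, rates, beta_params(), target, k = 3))
  message(sprintf(
    "%s: gamma = %.3g, W_app = %.2f kJ/mol, MSE %.2e -> %.2e", state,
    scan$gamma, scan$W_app, scan$mse_initial, scan$mse_final))
  message(sprintf("  populations: %s",
                  paste(sprintf("%s %.1f%% (subsampled %.1f +/- %.1f%%)",
                                pop$state, 100 * pop$fraction,
                                100 * sub$fraction[match(pop$state, sub$state)],
                                100 * sub$sd[match(pop$state, sub$state)]),
                        collapse = ", ")))
  pop$subsample_mean <- sub$fraction[match(pop$state, sub$state)]
  pop$subsample_sd <- sub$sd[match(pop$state, sub$state)]
  pop$target <- state
  pops[[state]] <- as.data.frame(pop)
}
utils::write.csv(do.call(rbind, pops), "results/populations.csv",
                 row.names = FALSE, quote = FALSE)
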