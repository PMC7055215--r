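#!/usr/bin/env Rscript
# Stage 5: the discounting x exploration correlation analysis.
#
# Crosses the six temporal-discounting measures (log10-transformed ks,
# raw number of "today" choices) with the ten model-free Horizon Task
# measures, prints the log k overall column, and reports the Fisher-z
# sample size for the design's target effect.

suppressPackageStartupMessages(library(kirbyhorizon))

scores <- read_output_csv("results/kirby_scores.csv")
metrics <- read_output_csv("results/horizon_metrics.csv")

tab <- correlation_table(scores, metrics)
write_output_csv(tab, "results/correlations.csv", seed = 2026L)

main <- tab[tab$discount_measure == "log_k_overall", ]
main$r <- round(main$r, 2)
main$p <- round(main$p, 3)
message("correlations with log10(k overall):")
print(main[, c("task_measure", "r", "p", "n")], row.names = FALSE)

n_req <- fisher_n_for_r(0.3, alpha = 0.05, power = 0.8, tails = 2)
message(sprintf(
  "Fisher-z sample size for r = 0.3 at alpha .05 (two-tailed), power .8: n = %d",
  n_req))
message("wrote results/correlations.csv")
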