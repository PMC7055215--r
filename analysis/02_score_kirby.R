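#!/usr/bin/env Rscript
# Stage 2: score the questionnaire.
#
# Converts each subject's 27 choices into the six temporal-discounting
# measures (overall k, the three magnitude-bin ks, their geometric mean,
# and the number of "today" choices) by maximum-consistency search over the
# item indifference points, then prints a range/mean/SD summary of the
# discounting indices.

suppressPackageStartupMessages(library(kirbyhorizon))

responses <- read_responses("results/responses.csv")
scores <- score_kirby(responses)
write_output_csv(scores, "results/kirby_scores.csv", seed = 2026L)

summ <- summarize_measures(scores, cols = c("k_overall", "k_small",
                                            "k_medium", "k_large",
                                            "k_geomean", "n_today"))
write_output_csv(summ, "results/kirby_summary.csv", seed = 2026L)

message(sprintf("scored %d subjects; discounting summary:", nrow(scores)))
print(transform(summ, min = signif(min, 3), max = signif(max, 3),
                mean = signif(mean, 3), sd = signif(sd, 3)))
message(sprintf("mean scoring consistency (overall): %.3f",
                mean(scores$consistency_overall)))
message("wrote results/kirby_scores.csv, results/kirby_summary.csv")
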