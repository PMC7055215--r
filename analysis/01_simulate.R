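#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study cohort.
#
# Draws 82 latent subjects (the study's sample size) with the default
# calibration: log-normal discount rates, horizon-specific information
# bonuses and decision noises coupled to log k through the latent
# correlation matrix, 32 Horizon Task games per horizon x condition cell,
# and logistic questionnaire responses at a $2 choice temperature.
# Writes the three raw tables under results/.

suppressPackageStartupMessages(library(kirbyhorizon))

seed <- 2026L
cfg <- population_config(n_subjects = 82, games_per_cell = 32, seed = seed)
sim <- simulate_study(cfg)

dir.create("results", showWarnings = FALSE)
write_output_csv(sim$truth, "results/truth.csv", seed = seed, config = cfg)
write_output_csv(sim$responses, "results/responses.csv", seed = seed,
                 config = cfg)
write_output_csv(sim$trials, "results/trials.csv", seed = seed, config = cfg)

message(sprintf("simulated %d subjects: %d questionnaire responses, %d trials",
                cfg$n_subjects, nrow(sim$responses), nrow(sim$trials)))
message(sprintf("true log10 k: mean %.2f, sd %.2f",
                mean(log10(sim$truth$true_k)), sd(log10(sim$truth$true_k))))
message("wrote results/truth.csv, results/responses.csv, results/trials.csv")
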