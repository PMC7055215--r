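#!/usr/bin/env Rscript
# Stage 3: model-free Horizon Task measures.
#
# Computes p(high info), p(low mean), accuracy and first-free reaction time
# per horizon for every subject, derives directed exploration (the horizon
# change in p(high info)) and random exploration (the change in p(low
# mean)), and runs the paired horizon contrasts with both effect-size
# conventions.

suppressPackageStartupMessages(library(kirbyhorizon))

trials <- read_trials("results/trials.csv")
metrics <- horizon_metrics(trials)
write_output_csv(metrics, "results/horizon_metrics.csv", seed = 2026L)

summ <- summarize_measures(metrics)
write_output_csv(summ, "results/horizon_summary.csv", seed = 2026L)
print(transform(summ, min = round(min, 4), max = round(max, 4),
                mean = round(mean, 4), sd = round(sd, 4)))

t_low <- paired_t(metrics$p_low_mean_h1, metrics$p_low_mean_h6)
t_high <- paired_t(metrics$p_high_info_h1, metrics$p_high_info_h6)
tests <- rbind(cbind(contrast = "p_low_mean_h6_vs_h1", t_low),
               cbind(contrast = "p_high_info_h6_vs_h1", t_high))
write_output_csv(tests, "results/horizon_contrasts.csv", seed = 2026L)

message(sprintf(
  "horizon increase in p(low mean):  t(%d) = %.2f, p = %.4g, d_av = %.2f",
  t_low$df, t_low$t, t_low$p, t_low$d_av))
message(sprintf(
  "horizon increase in p(high info): t(%d) = %.2f, p = %.4g, d_av = %.2f",
  t_high$df, t_high$t, t_high$p, t_high$d_av))
message("wrote results/horizon_metrics.csv, results/horizon_summary.csv, ",
        "results/horizon_contrasts.csv")
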