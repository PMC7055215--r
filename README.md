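# kirbyhorizon

Tools for studying how **temporal discounting** relates to
**explore–exploit behavior**, for researchers in decision neuroscience and
behavioral science. The package implements the full analysis chain of an
individual-differences study design:

1. **Questionnaire scoring** — the 27-item monetary choice questionnaire is
   scored into hyperbolic discount rates. Each item (immediate amount *I*,
   delayed amount *A*, delay *D* days) defines an indifference point
   *k\** = (*A*/*I* − 1)/*D* under the hyperbolic value model
   *V* = *A*/(1 + *kD*); a subject's rate is the candidate maximizing
   consistency with their pattern of "today"/"later" choices, overall and
   within three reward-magnitude bins.
2. **Horizon Task measures** — from two-armed Gaussian bandit games
   (reward SD 8 points, 4 forced trials, then 1 or 6 free choices):
   p(high info), p(low mean), accuracy and reaction time per horizon, with
   **directed exploration** = Δp(high info) and **random exploration** =
   Δp(low mean) across horizons.
3. **Model-based quantification** — a logistic first-free-choice model,
   p(right) = 1/(1 + exp(−(ΔR + A·ΔI + b)/σ)), fit per subject × horizon by
   bounded multi-start maximum likelihood, yielding an information bonus
   *A*, side bias *b* and decision noise σ.
4. **Statistics** — paired contrasts with both d_z and the average-variance
   effect size d_av, a 6 × 10 Pearson correlation grid between discounting
   and task measures, and Fisher-z sample-size calculation.
5. **Synthetic cohorts** — a seeded generator draws latent subjects from a
   Gaussian copula over (log k, information bonuses, log decision noises)
   with configurable cross-trait correlations, emits questionnaire
   responses and full trial logs, and lets every stage above be validated
   by parameter recovery.

See `vignettes/kirbyhorizon-methods.Rmd` for the models, calibration and
numerical conventions.

## Worked example

The numbered scripts under `analysis/` run the whole study pipeline on a
simulated 82-subject cohort and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R        # cohort, responses, trial logs
Rscript analysis/02_score_kirby.R     # discounting measures
Rscript analysis/03_horizon_metrics.R # model-free task measures + contrasts
Rscript analysis/04_fit_model.R       # logistic model fits
Rscript analysis/05_correlate.R       # discounting x exploration grid
```

Stage 3 prints the horizon contrasts:

```
horizon increase in p(low mean):  t(81) = 3.56, p = 0.0006148, d_av = 0.43
horizon increase in p(high info): t(81) = 0.80, p = 0.4265, d_av = 0.09
```

i.e. this simulated cohort, like the population it is calibrated to, shows
a clear horizon increase in behavioral variability (random exploration) and
a smaller, unreliable increase in information seeking. Stage 5 prints the
correlations between log10 overall discount rate and the task measures:

```
   task_measure     r     p  n
       directed -0.25 0.025 82
         random  0.00 0.995 82
 p_high_info_h1  0.40 0.000 82
```

— steeper discounters explore less in the directed sense but no differently
in the random sense, with the directed effect driven by horizon-1
uncertainty preference; all three reflect the latent correlations the
generator was configured with (−0.30, null, +0.35) after measurement
attenuation at 32 games per cell. Stage 5 also reports the Fisher-z sample
size for detecting r = 0.3 (α = .05 two-tailed, power .8): **n = 85**.

In code, the same pipeline is three calls:

```r
library(kirbyhorizon)
sim <- simulate_study(population_config(n_subjects = 82, seed = 2026))
scores <- score_kirby(sim$responses)        # six discounting measures
metrics <- horizon_metrics(sim$trials)      # ten task measures
correlation_table(scores, metrics)          # 6 x 10 grid of (r, p, n)
```

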