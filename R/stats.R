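#' Paired t-test from summary statistics
#'
#' Computes the paired (dependent-sample) t statistic, its two-tailed
#' p-value and both paired effect-size conventions from summary statistics
#' of the paired difference: `t = mean_diff / (sd_diff / sqrt(n))` on
#' `n - 1` degrees of freedom, `d_z = mean_diff / sd_diff`, and
#' `d_av = mean_diff / sqrt((sd_a^2 + sd_b^2) / 2)` (available when the two
#' condition SDs are supplied).
#'
#' @param n number of pairs.
#' @param mean_diff mean of the pairwise differences (b - a).
#' @param sd_diff SD of the pairwise differences.
#' @param sd_a,sd_b optional SDs of the two conditions (for `d_av`).
#' @param mean_a,mean_b optional condition means (reported back only).
#' @return one-row data.frame: `n`, `mean_a`, `mean_b`, `mean_diff`, `sd_a`,
#'   `sd_b`, `sd_diff`, `t`, `df`, `p` (two-tailed), `d_av`, `d_z`,
#'   `degenerate` (TRUE when `sd_diff` is zero).
#' @examples
#' paired_t_summary(n = 82, mean_diff = 0.0671, sd_diff = 0.1571,
#'                  sd_a = 0.1757, sd_b = 0.1624)
#' @export
paired_t_summary <- function(n, mean_diff, sd_diff,
                             sd_a = NA_real_, sd_b = NA_real_,
                             mean_a = NA_real_, mean_b = NA_real_) {
  if (n < 3) stop("need at least 3 pairs")
  if (sd_diff < 0) stop("sd_diff must be nonnegative")
  degenerate <- sd_diff == 0
  tval <- if (degenerate) NA_real_ else mean_diff / (sd_diff / sqrt(n))
  df <- n - 1
  p <- if (degenerate) NA_real_ else 2 * pt(-abs(tval), df)
  d_av <- if (is.na(sd_a) || is.na(sd_b)) NA_real_
          else cohen_d_av(mean_diff, sd_a, sd_b)
  d_z <- if (degenerate) NA_real_ else mean_diff / sd_diff
  data.frame(n = n, mean_a = mean_a, mean_b = mean_b, mean_diff = mean_diff,
             sd_a = sd_a, sd_b = sd_b, sd_diff = sd_diff,
             t = tval, df = df, p = p, d_av = d_av, d_z = d_z,
             degenerate = degenerate)
}

#' Paired t-test on raw vectors
#'
#' Convenience wrapper computing the summaries of `b - a` and delegating to
#' [paired_t_summary()]; the difference is taken as `b - a`, so a positive
#' `t` means `b > a` on average.
#'
#' @param a,b paired numeric vectors of equal length (>= 3), `NA` pairs
#'   dropped.
#' @return see [paired_t_summary()].
#' @examples
#' paired_t(rnorm(20), rnorm(20, 0.5))
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  ok <- !(is.na(a) | is.na(b))
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3) stop("need at least 3 complete pairs")
  d <- b - a
  paired_t_summary(n = length(d), mean_diff = mean(d), sd_diff = sd(d),
                   sd_a = sd(a), sd_b = sd(b),
                   mean_a = mean(a), mean_b = mean(b))
}

#' Average-variance Cohen's d for paired designs
#'
#' `d_av = mean_diff / sqrt((sd_a^2 + sd_b^2) / 2)`: the mean difference
#' scaled by the root-mean-square of the two condition SDs. This convention
#' (rather than `d_z`, which scales by the SD of the differences) is the one
#' under which a paired design's effect size is comparable to a
#' between-group d.
#'
#' @param mean_diff mean pairwise difference.
#' @param sd_a,sd_b condition SDs (> 0).
#' @return effect size (unitless).
#' @examples
#' cohen_d_av(0.0671, 0.1757, 0.1624)  # ~0.40
#' @export
cohen_d_av <- function(mean_diff, sd_a, sd_b) {
  if (any(c(sd_a, sd_b) <= 0)) stop("condition SDs must be positive")
  mean_diff / sqrt((sd_a^2 + sd_b^2) / 2)
}

#' Pearson correlation grid between discounting and task measures
#'
#' Correlates each temporal-discounting measure with each Horizon Task
#' measure over subjects, pairwise-complete, reporting Pearson's r, the
#' two-tailed p-value from `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2`
#' df, and the pair count per cell. Discount rates are log10-transformed
#' before correlating (the number of "today" choices is used untransformed).
#' Cells with fewer than 4 complete pairs are returned as `NA`.
#'
#' @param scores per-subject discounting table (from [score_kirby()]); the
#'   columns `k_overall`, `k_small`, `k_medium`, `k_large`, `k_geomean`,
#'   `n_today` are used.
#' @param metrics per-subject task table (from [horizon_metrics()]); the
#'   columns `directed`, `random`, `p_high_info_h1`, `p_high_info_h6`,
#'   `p_low_mean_h1`, `p_low_mean_h6`, `accuracy_h1`, `accuracy_h6`,
#'   `rt_h1`, `rt_h6` are used.
#' @param bonferroni also report Bonferroni-adjusted p-values (off by
#'   default; no multiple-testing correction is applied otherwise).
#' @return long data.frame, one row per (discount measure, task measure)
#'   cell: `discount_measure`, `task_measure`, `r`, `p`, `n` (and
#'   `p_bonferroni` if requested).
#' @export
correlation_table <- function(scores, metrics, bonferroni = FALSE) {
  merged <- merge(scores, metrics, by = "subject_id")
  dcols <- c(log_k_overall = "k_overall", log_k_small = "k_small",
             log_k_medium = "k_medium", log_k_large = "k_large",
             log_k_geomean = "k_geomean", n_today = "n_today")
  tcols <- c("directed", "random", "p_high_info_h1", "p_high_info_h6",
             "p_low_mean_h1", "p_low_mean_h6", "accuracy_h1", "accuracy_h6",
             "rt_h1", "rt_h6")
  miss <- setdiff(c(unname(dcols), tcols), names(merged))
  if (length(miss))
    stop("missing measure column(s): ", paste(miss, collapse = ", "))
  grid <- expand.grid(discount_measure = names(dcols), task_measure = tcols,
                      stringsAsFactors = FALSE)
  cellfn <- function(dm, tm) {
    x <- merged[[dcols[dm]]]
    if (startsWith(dm, "log_k")) x <- log10(x)
    y <- merged[[tm]]
    ok <- !(is.na(x) | is.na(y))
    n <- sum(ok)
    if (n < 4) return(c(NA_real_, NA_real_, n))
    ct <- cor.test(x[ok], y[ok], method = "pearson")
    c(unname(ct$estimate), ct$p.value, n)
  }
  vals <- t(mapply(cellfn, grid$discount_measure, grid$task_measure))
  out <- data.frame(grid, r = vals[, 1], p = vals[, 2], n = as.integer(vals[, 3]))
  if (bonferroni) out$p_bonferroni <- pmin(1, out$p * nrow(out))
  rownames(out) <- NULL
  out
}

#' Sample size for detecting a correlation (Fisher-z approximation)
#'
#' Smallest `n` achieving the target power for a two- or one-tailed test of
#' a Pearson correlation `r` at level `alpha`, under the Fisher
#' z-transformation approximation:
#' `n = ceil(((z_alpha + z_power) / atanh(r))^2 + 3)`, bounded below by 4.
#'
#' @param r hypothesized correlation, in (0, 1).
#' @param alpha significance level (default 0.05).
#' @param power target power (default 0.8).
#' @param tails 1 or 2 (default 2).
#' @return integer sample size.
#' @examples
#' fisher_n_for_r(0.3)  # 85
#' @export
fisher_n_for_r <- function(r, alpha = 0.05, power = 0.8, tails = 2) {
  if (!is.finite(r) || r <= 0 || r >= 1)
    stop("r must lie strictly between 0 and 1")
  if (!tails %in% c(1, 2)) stop("tails must be 1 or 2")
  za <- qnorm(1 - alpha / tails)
  zb <- qnorm(power)
  C <- atanh(r)
  max(4L, as.integer(ceiling(((za + zb) / C)^2 + 3)))
}

#' Range/mean/SD summary of task or discounting measures
#'
#' Summarizes selected per-subject columns as min, max, mean and SD — the
#' shape of a descriptive results table.
#'
#' @param df per-subject data.frame.
#' @param cols columns to summarize (default: the six model-free task
#'   measures if present, otherwise all numeric columns).
#' @return data.frame with `measure`, `min`, `max`, `mean`, `sd`.
#' @export
summarize_measures <- function(df, cols = NULL) {
  if (is.null(cols)) {
    task_default <- c("p_high_info_h1", "p_high_info_h6", "p_low_mean_h1",
                      "p_low_mean_h6", "directed", "random")
    cols <- if (all(task_default %in% names(df))) task_default
            else names(df)[vapply(df, is.numeric, logical(1))]
  }
  rows <- lapply(cols, function(cl) {
    x <- df[[cl]]
    x <- x[!is.na(x)]
    data.frame(measure = cl, min = min(x), max = max(x),
               mean = mean(x), sd = sd(x))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
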