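#' Configuration for the synthetic study generator
#'
#' Bundles every knob of the generator: population size, latent trait
#' distributions, the latent correlation structure, questionnaire choice
#' noise, and the Horizon Task design (games per horizon x condition cell,
#' Gaussian payoff SD fixed at 8 points, generative mean offsets).
#'
#' Latent traits are drawn from a multivariate Gaussian (a Gaussian copula on
#' the transformed scale) over the vector
#' `(log k, info_bonus_h1, d_info_bonus, log_noise_h1, d_log_noise)`, where
#' `d_info_bonus = info_bonus_h6 - info_bonus_h1` and
#' `d_log_noise = log(noise_h6) - log(noise_h1)`. Parametrizing the
#' horizon-6 traits as increments lets cross-trait correlations with the
#' horizon *change* (directed / random exploration) be configured directly.
#' `k` and the decision noises are log-normal; `k` is clipped to
#' `[K_FLOOR, K_CEIL]`.
#'
#' Defaults are calibrated so that a simulated cohort of 82 subjects playing
#' 32 games per cell reproduces the group-level behavior of a typical
#' undergraduate sample on this task battery (group means of p(high info)
#' and p(low mean) by horizon of about 0.51/0.55 and 0.29/0.36, discount
#' rates log-normal around 0.012/day), with latent correlations between
#' log k and the exploration traits of +0.35 (info bonus, horizon 1), -0.30
#' (horizon change in info bonus), +0.22 (log noise, horizon 1) and +0.04
#' (horizon change in log noise).
#'
#' @param n_subjects number of simulated subjects.
#' @param games_per_cell Horizon Task games per horizon x condition cell.
#' @param seed integer seed consumed by [simulate_study()].
#' @param log_k_mean,log_k_sd latent natural-log discount rate.
#' @param info_bonus_h1_mean,info_bonus_h1_sd horizon-1 information bonus
#'   (points).
#' @param d_info_bonus_mean,d_info_bonus_sd horizon-6 minus horizon-1
#'   information bonus (points).
#' @param log_noise_h1_mean,log_noise_h1_sd horizon-1 decision noise on the
#'   natural-log scale (points after exp).
#' @param d_log_noise_mean,d_log_noise_sd horizon change of log decision
#'   noise.
#' @param side_bias_sd SD of the stable right-side bias (points).
#' @param kirby_choice_noise logistic temperature (dollars) of the
#'   questionnaire responder; 0 gives the deterministic responder.
#' @param trait_cor 5 x 5 latent correlation matrix over
#'   `(log_k, info_bonus_h1, d_info_bonus, log_noise_h1, d_log_noise)`.
#' @param mean_range range of the uniform base generative bandit mean.
#' @param mean_offsets candidate absolute differences between the two
#'   generative means (a sign is drawn separately).
#' @param reward_sd payout SD (points).
#' @param rt_meanlog,rt_sdlog log-normal first-free reaction-time nuisance
#'   parameters (seconds).
#' @return a list of class `population_config`.
#' @examples
#' cfg <- population_config(n_subjects = 10, seed = 42)
#' @export
population_config <- function(n_subjects = 82,
                              games_per_cell = 32,
                              seed = 1L,
                              log_k_mean = -4.4, log_k_sd = 1.5,
                              info_bonus_h1_mean = 1.4,
                              info_bonus_h1_sd = 8.6,
                              d_info_bonus_mean = 4.6,
                              d_info_bonus_sd = 10,
                              log_noise_h1_mean = log(14),
                              log_noise_h1_sd = 1.1,
                              d_log_noise_mean = 0.65,
                              d_log_noise_sd = 0.7,
                              side_bias_sd = 3,
                              kirby_choice_noise = 2,
                              trait_cor = default_trait_cor(),
                              mean_range = c(40, 60),
                              mean_offsets = c(4, 8, 12, 20, 30),
                              reward_sd = 8,
                              rt_meanlog = -0.1, rt_sdlog = 0.4) {
  cfg <- list(n_subjects = n_subjects, games_per_cell = games_per_cell,
              seed = seed,
              log_k_mean = log_k_mean, log_k_sd = log_k_sd,
              info_bonus_h1_mean = info_bonus_h1_mean,
              info_bonus_h1_sd = info_bonus_h1_sd,
              d_info_bonus_mean = d_info_bonus_mean,
              d_info_bonus_sd = d_info_bonus_sd,
              log_noise_h1_mean = log_noise_h1_mean,
              log_noise_h1_sd = log_noise_h1_sd,
              d_log_noise_mean = d_log_noise_mean,
              d_log_noise_sd = d_log_noise_sd,
              side_bias_sd = side_bias_sd,
              kirby_choice_noise = kirby_choice_noise,
              trait_cor = trait_cor,
              mean_range = mean_range, mean_offsets = mean_offsets,
              reward_sd = reward_sd,
              rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog)
  class(cfg) <- "population_config"
  validate_config(cfg)
  cfg
}

#' Default latent trait correlation matrix
#'
#' Correlations over `(log_k, info_bonus_h1, d_info_bonus, log_noise_h1,
#' d_log_noise)`. The log k row encodes the discounting x exploration
#' structure the generator emulates: +0.35 with the horizon-1 information
#' bonus, -0.30 with its horizon change (directed exploration), +0.22 with
#' horizon-1 log noise, +0.04 with its horizon change (random exploration).
#' The within-task entries (-0.15 between info bonus and its change, -0.455
#' between log noise and its change) keep the implied horizon-6 trait
#' spreads near those of the horizon-1 traits.
#'
#' @return a 5 x 5 correlation matrix.
#' @export
default_trait_cor <- function() {
  nm <- c("log_k", "info_bonus_h1", "d_info_bonus",
          "log_noise_h1", "d_log_noise")
  R <- diag(5)
  dimnames(R) <- list(nm, nm)
  R["log_k", "info_bonus_h1"] <- R["info_bonus_h1", "log_k"] <- 0.35
  R["log_k", "d_info_bonus"] <- R["d_info_bonus", "log_k"] <- -0.30
  R["log_k", "log_noise_h1"] <- R["log_noise_h1", "log_k"] <- 0.22
  R["log_k", "d_log_noise"] <- R["d_log_noise", "log_k"] <- 0.04
  R["info_bonus_h1", "d_info_bonus"] <-
    R["d_info_bonus", "info_bonus_h1"] <- -0.15
  R["log_noise_h1", "d_log_noise"] <-
    R["d_log_noise", "log_noise_h1"] <- -0.455
  R
}

validate_config <- function(cfg) {
  R <- cfg$trait_cor
  if (!is.matrix(R) || !identical(dim(R), c(5L, 5L)))
    stop("trait_cor must be a 5 x 5 matrix")
  if (max(abs(R - t(R))) > 1e-8 || any(abs(diag(R) - 1) > 1e-8))
    stop("trait_cor must be symmetric with unit diagonal")
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("trait_cor must be positive semidefinite")
  sds <- c(cfg$log_k_sd, cfg$info_bonus_h1_sd, cfg$d_info_bonus_sd,
           cfg$log_noise_h1_sd, cfg$d_log_noise_sd, cfg$side_bias_sd)
  if (any(sds < 0)) stop("trait SDs must be nonnegative")
  if (cfg$n_subjects <= 0 || cfg$games_per_cell <= 0)
    stop("n_subjects and games_per_cell must be positive")
  if (cfg$kirby_choice_noise < 0)
    stop("kirby_choice_noise must be nonnegative")
  invisible(cfg)
}

#' Draw a latent population
#'
#' Samples `n_subjects` latent subjects from the configured multivariate
#' Gaussian, transforms (`k = exp(log_k)` clipped to `[K_FLOOR, K_CEIL]`,
#' `noise = exp(log noise)`) and derives the horizon-6 traits from the
#' horizon-1 traits plus their increments. Draws from the current RNG
#' stream; use [simulate_study()] for seeded end-to-end generation.
#'
#' @param config a [population_config()].
#' @return data.frame, one row per subject: `subject_id`, `true_k`,
#'   `info_bonus_h1`, `info_bonus_h6`, `noise_h1`, `noise_h6`, `side_bias`,
#'   and the raw latent columns `latent_log_k`, `latent_info_bonus_h1`,
#'   `latent_d_info_bonus`, `latent_log_noise_h1`, `latent_d_log_noise`.
#' @export
gen_population <- function(config) {
  validate_config(config)
  n <- config$n_subjects
  mu <- c(config$log_k_mean, config$info_bonus_h1_mean,
          config$d_info_bonus_mean, config$log_noise_h1_mean,
          config$d_log_noise_mean)
  sds <- c(config$log_k_sd, config$info_bonus_h1_sd, config$d_info_bonus_sd,
           config$log_noise_h1_sd, config$d_log_noise_sd)
  Sigma <- config$trait_cor * tcrossprod(sds)
  Z <- MASS::mvrnorm(n, mu = mu, Sigma = Sigma)
  Z <- matrix(Z, nrow = n)  # keep matrix shape at n = 1
  log_k <- pmin(pmax(Z[, 1], log(K_FLOOR)), log(K_CEIL))
  data.frame(
    subject_id = sprintf("s%04d", seq_len(n)),
    true_k = exp(log_k),
    info_bonus_h1 = Z[, 2],
    info_bonus_h6 = Z[, 2] + Z[, 3],
    noise_h1 = exp(Z[, 4]),
    noise_h6 = exp(Z[, 4] + Z[, 5]),
    side_bias = rnorm(n, 0, config$side_bias_sd),
    latent_log_k = Z[, 1],
    latent_info_bonus_h1 = Z[, 2],
    latent_d_info_bonus = Z[, 3],
    latent_log_noise_h1 = Z[, 4],
    latent_d_log_noise = Z[, 5],
    stringsAsFactors = FALSE
  )
}

#' Simulate questionnaire responses for a population
#'
#' Each subject values the delayed option hyperbolically at their true
#' discount rate and chooses "today" with probability
#' `plogis((immediate - V_delayed) / choice_noise)`; `choice_noise = 0`
#' gives the deterministic responder ("today" whenever the immediate amount
#' is at least the discounted delayed value).
#'
#' @param population data.frame from [gen_population()].
#' @param instrument instrument data.frame; defaults to the packaged one.
#' @param choice_noise logistic temperature in dollars.
#' @return long response table: `subject_id`, `item_index`, `choice`.
#' @export
gen_kirby_responses <- function(population,
                                instrument = kirby_instrument(),
                                choice_noise = 2) {
  n <- nrow(population)
  m <- nrow(instrument)
  k <- rep(population$true_k, each = m)
  v <- hyperbolic_value(rep(instrument$delayed, n),
                        rep(instrument$delay_days, n), k)
  adv_today <- rep(instrument$immediate, n) - v
  p_today <- if (choice_noise == 0) as.numeric(adv_today >= 0)
             else plogis(adv_today / choice_noise)
  today <- rbinom(n * m, 1, p_today) == 1
  data.frame(
    subject_id = rep(population$subject_id, each = m),
    item_index = rep(instrument$index, n),
    choice = ifelse(today, "today", "later"),
    stringsAsFactors = FALSE
  )
}

#' Simulate Horizon Task trial logs for a population
#'
#' Generates, per subject, `games_per_cell` games in each horizon x
#' information-condition cell. Each game draws one generative mean uniformly
#' on `mean_range` and offsets the other side by a signed draw from
#' `mean_offsets`; four forced trials (sides balanced across games within
#' each cell: `{2,2}` in the equal condition, once-played side alternating
#' in the unequal condition) pay Gaussian rewards with SD `reward_sd`. The
#' first free choice follows [choice_prob()] with the subject's
#' horizon-specific parameters applied to the observed forced means; in
#' horizon 6 the remaining five free choices are drawn from the same
#' (frozen) probability as nuisance filler — within-game learning is not
#' modelled. Reaction times are log-normal nuisance draws.
#'
#' @param population data.frame from [gen_population()].
#' @param config a [population_config()].
#' @return long trial log (see [games_from_trials()] for the schema).
#' @export
gen_horizon_games <- function(population, config) {
  validate_config(config)
  gpc <- config$games_per_cell
  n_sub <- nrow(population)
  cells <- expand.grid(horizon = c(1L, 6L),
                       info_condition = c("unequal_13", "equal_22"),
                       rep = seq_len(gpc),
                       subj = seq_len(n_sub),
                       stringsAsFactors = FALSE)
  N <- nrow(cells)
  subj <- cells$subj
  horizon <- cells$horizon
  uneq <- cells$info_condition == "unequal_13"

  base <- runif(N, config$mean_range[1], config$mean_range[2])
  delta <- sample(config$mean_offsets, N, replace = TRUE) *
    sample(c(-1, 1), N, replace = TRUE)
  mean_left <- base
  mean_right <- base + delta

  # forced-side layout: exact balance of the once-played side across the
  # games of each unequal cell (odd remainders randomized)
  once_right <- logical(N)
  once_right[uneq] <- (cells$rep[uneq] %% 2L) == 0L
  odd <- uneq & cells$rep == gpc & (gpc %% 2L == 1L)
  once_right[odd] <- runif(sum(odd)) < 0.5
  n_right_forced <- ifelse(uneq, ifelse(once_right, 1L, 3L), 2L)

  # forced rewards: 4 draws per game, the right-side positions picked by
  # ranking random keys (vectorized per-game permutation)
  keys <- matrix(runif(4 * N), N, 4)
  rank_key <- matrix(1L, N, 4)
  for (j in 1:4) for (i in 1:4) if (i != j)
    rank_key[, j] <- rank_key[, j] + (keys[, i] < keys[, j])
  forced_side <- matrix("left", N, 4)
  forced_side[rank_key <= n_right_forced] <- "right"
  forced_mean <- matrix(ifelse(forced_side == "right", mean_right, mean_left),
                        N, 4)
  forced_reward <- matrix(rnorm(4 * N, forced_mean, config$reward_sd), N, 4)

  is_right <- forced_side == "right"
  sum_r <- rowSums(forced_reward * is_right)
  sum_l <- rowSums(forced_reward * !is_right)
  dR_obs <- sum_r / n_right_forced - sum_l / (4 - n_right_forced)
  dI <- ifelse(uneq, ifelse(once_right, 1L, -1L), 0L)

  ib <- ifelse(horizon == 1L, population$info_bonus_h1[subj],
               population$info_bonus_h6[subj])
  noise <- ifelse(horizon == 1L, population$noise_h1[subj],
                  population$noise_h6[subj])
  bias <- population$side_bias[subj]
  p_right <- plogis((dR_obs + ib * dI + bias) / noise)

  n_free <- ifelse(horizon == 1L, 1L, 6L)
  free_right <- matrix(NA, N, 6)
  free_reward <- matrix(NA_real_, N, 6)
  free_rt <- matrix(NA_real_, N, 6)
  for (j in 1:6) {
    live <- j <= n_free
    nn <- sum(live)
    fr <- rbinom(nn, 1, p_right[live]) == 1
    free_right[live, j] <- fr
    mu <- ifelse(fr, mean_right[live], mean_left[live])
    free_reward[live, j] <- rnorm(nn, mu, config$reward_sd)
    free_rt[live, j] <- rlnorm(nn, config$rt_meanlog, config$rt_sdlog)
  }

  subject_id <- population$subject_id[subj]
  game_id <- sprintf("g%05d", stats::ave(seq_len(N), subj, FUN = seq_along))

  forced_blocks <- lapply(1:4, function(j) {
    data.frame(subject_id = subject_id, game_id = game_id,
               horizon = horizon, info_condition = cells$info_condition,
               trial_index = j, forced = 1L,
               side = forced_side[, j], reward = forced_reward[, j],
               rt = NA_real_,
               mean_left = mean_left, mean_right = mean_right,
               stringsAsFactors = FALSE)
  })
  free_blocks <- lapply(1:6, function(j) {
    live <- j <= n_free
    data.frame(subject_id = subject_id[live], game_id = game_id[live],
               horizon = horizon[live],
               info_condition = cells$info_condition[live],
               trial_index = 4L + j, forced = 0L,
               side = ifelse(free_right[live, j], "right", "left"),
               reward = free_reward[live, j], rt = free_rt[live, j],
               mean_left = mean_left[live], mean_right = mean_right[live],
               stringsAsFactors = FALSE)
  })
  trials <- rbind(do.call(rbind, forced_blocks), do.call(rbind, free_blocks))
  trials <- trials[order(trials$subject_id, trials$game_id,
                         trials$trial_index), ]
  rownames(trials) <- NULL
  trials
}

#' Simulate a full synthetic study
#'
#' Seeds the RNG once from `config$seed` and draws, in order, the latent
#' population, the questionnaire responses and the Horizon Task trial log,
#' so a config (including its seed) fully determines the data.
#'
#' @param config a [population_config()].
#' @return list with `truth` (latent population), `responses`
#'   (questionnaire long table), `trials` (Horizon Task trial log) and
#'   `config`.
#' @examples
#' sim <- simulate_study(population_config(n_subjects = 3,
#'                                         games_per_cell = 4, seed = 7))
#' names(sim)
#' @export
simulate_study <- function(config) {
  validate_config(config)
  set.seed(config$seed)
  truth <- gen_population(config)
  responses <- gen_kirby_responses(truth, kirby_instrument(),
                                   choice_noise = config$kirby_choice_noise)
  trials <- gen_horizon_games(truth, config)
  list(truth = truth, responses = responses, trials = trials,
       config = config)
}
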