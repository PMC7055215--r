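# shared helpers: tiny constructors and independent oracles used across tests

# one-row latent population with identical traits in both horizons
make_subject <- function(ib, noise, bias = 0, k = 0.01, id = "x") {
  data.frame(subject_id = id, true_k = k,
             info_bonus_h1 = ib, info_bonus_h6 = ib,
             noise_h1 = noise, noise_h6 = noise, side_bias = bias,
             stringsAsFactors = FALSE)
}

# deterministic questionnaire responder: today iff true k > item indifference k
det_profile <- function(k, instrument = kirby_instrument()) {
  ifelse(k > indifference_k(instrument), "today", "later")
}

# oracle consistency of an arbitrary candidate rate, by direct evaluation of
# the choice rule (equality with an item's indifference point matches either
# choice)
grid_consistency <- function(k, items, choices) {
  item_k <- indifference_k(items)
  pred_today <- k > item_k
  tie <- abs(k - item_k) <= 1e-12 * pmax(k, item_k)
  mean(tie | (pred_today == (choices == "today")))
}

# hand-built trial log: one game from a compact description
build_game <- function(subject, gid, horizon, cond, ml, mr,
                       forced_sides, free_sides, rt1 = 0.7) {
  n_free <- if (horizon == 1) 1L else 6L
  stopifnot(length(forced_sides) == 4, length(free_sides) == n_free)
  data.frame(
    subject_id = subject, game_id = gid, horizon = horizon,
    info_condition = cond, trial_index = seq_len(4L + n_free),
    forced = rep(c(1L, 0L), c(4L, n_free)),
    side = c(forced_sides, free_sides),
    reward = 50, rt = c(rep(NA_real_, 4), rt1, rep(0.5, n_free - 1L)),
    mean_left = ml, mean_right = mr, stringsAsFactors = FALSE
  )
}

# eight-game fixture (two per horizon x condition cell) plus one tied-means
# game; every first free choice is hand-chosen so the fractions are known
hand_fixture <- function() {
  rbind(
    build_game("s1", "gA", 1, "unequal_13", 50, 30,
               c("left", "right", "left", "left"), "right", rt1 = 0.4),
    build_game("s1", "gB", 1, "unequal_13", 40, 60,
               c("right", "left", "right", "right"), "right", rt1 = 0.6),
    build_game("s1", "gC", 1, "equal_22", 60, 40,
               c("left", "left", "right", "right"), "left", rt1 = 0.8),
    build_game("s1", "gD", 1, "equal_22", 55, 45,
               c("left", "right", "left", "right"), "right", rt1 = 1.0),
    build_game("s1", "gE", 6, "unequal_13", 48, 52,
               c("left", "left", "left", "right"),
               c("right", rep("left", 5))),
    build_game("s1", "gF", 6, "unequal_13", 60, 40,
               c("right", "right", "right", "left"),
               c("right", rep("left", 5))),
    build_game("s1", "gG", 6, "equal_22", 40, 60,
               c("left", "right", "right", "left"),
               c("left", rep("left", 5))),
    build_game("s1", "gH", 6, "equal_22", 60, 40,
               c("right", "left", "left", "right"),
               c("left", rep("left", 5))),
    build_game("s1", "gI", 1, "equal_22", 50, 50,
               c("left", "right", "left", "right"), "left", rt1 = 0.2)
  )
}

# single-subject games at one horizon: n games per information condition
one_horizon_games <- function(ib, noise, n_per_cond, seed,
                              bias = 0, horizon = 1) {
  cfg <- population_config(n_subjects = 1, games_per_cell = n_per_cond,
                           seed = seed)
  set.seed(seed)
  tr <- gen_horizon_games(make_subject(ib, noise, bias), cfg)
  g <- games_from_trials(tr)
  g[g$horizon == horizon, , drop = FALSE]
}

# minimum negative log-likelihood over a dense grid on the fit bounds
grid_nll_min <- function(g, len = 21) {
  b <- horizon_fit_bounds()
  ibs <- seq(b$lower[1], b$upper[1], length.out = len)
  bs <- seq(b$lower[2], b$upper[2], length.out = len)
  lns <- seq(b$lower[3], b$upper[3], length.out = len)
  gg <- as.matrix(expand.grid(ibs, bs, lns))
  z <- outer(gg[, 1], as.numeric(g$dI))
  z <- sweep(z, 2, g$dR, "+") + gg[, 2]
  z <- z / exp(gg[, 3])
  y <- matrix(g$first_right, nrow(gg), ncol(z), byrow = TRUE)
  min(rowSums(log1p(exp(-abs(z))) + pmax(z, 0) - y * z))
}
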