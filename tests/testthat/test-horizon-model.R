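test_that("choice probabilities are symmetric and respect limits", {
  p0 <- choice_prob(list(info_bonus = 0, side_bias = 0, noise = 8),
                    dR = 0, dI = 0)
  expect_equal(p0, 0.5)
  # huge noise washes out any finite evidence
  expect_equal(choice_prob(list(info_bonus = 5, side_bias = 3, noise = 1e6),
                           dR = 40, dI = 1), 0.5, tolerance = 1e-4)
  # a 10-point bonus exactly cancels a 10-point reward deficit
  expect_equal(choice_prob(list(info_bonus = 10, side_bias = 0, noise = 8),
                           dR = -10, dI = 1), 0.5)
  # relabeling sides maps p to 1 - p
  pr <- choice_prob(list(info_bonus = 7, side_bias = 2, noise = 5),
                    dR = 3, dI = 1)
  pl <- choice_prob(list(info_bonus = 7, side_bias = -2, noise = 5),
                    dR = -3, dI = -1)
  expect_equal(pr, 1 - pl)
  expect_error(choice_prob(list(info_bonus = 0, side_bias = 0, noise = 0),
                           dR = 0, dI = 0), "positive")
})

test_that("negative log-likelihood is Bernoulli, additive, order-invariant", {
  params <- list(info_bonus = 0, side_bias = 0, noise = 8)
  one <- data.frame(dR = 0, dI = 0, first_right = 1)
  expect_equal(neg_log_lik(params, one), log(2))
  set.seed(3)
  g <- one_horizon_games(ib = 10, noise = 8, n_per_cond = 50, seed = 3)
  expect_equal(neg_log_lik(params, rbind(g, g)), 2 * neg_log_lik(params, g))
  expect_equal(neg_log_lik(params, g[sample(nrow(g)), ]),
               neg_log_lik(params, g))
  expect_gte(neg_log_lik(params, g), 0)
})

test_that("the likelihood prefers the generating parameters", {
  g <- one_horizon_games(ib = 10, noise = 8, n_per_cond = 250, seed = 4)
  truth <- list(info_bonus = 10, side_bias = 0, noise = 8)
  for (far in list(list(info_bonus = -20, side_bias = 0, noise = 8),
                   list(info_bonus = 10, side_bias = 40, noise = 8),
                   list(info_bonus = 10, side_bias = 0, noise = 100))) {
    expect_lt(neg_log_lik(truth, g), neg_log_lik(far, g))
  }
})

test_that("analytic gradient matches a numerical gradient", {
  g <- one_horizon_games(ib = 5, noise = 12, n_per_cond = 40, seed = 5)
  par <- c(4, -1, log(9))
  eps <- 1e-6
  num <- vapply(1:3, function(i) {
    e <- numeric(3); e[i] <- eps
    (kirbyhorizon:::.nll(par + e, g$dR, g$dI, g$first_right) -
     kirbyhorizon:::.nll(par - e, g$dR, g$dI, g$first_right)) / (2 * eps)
  }, numeric(1))
  expect_equal(kirbyhorizon:::.nll_grad(par, g$dR, g$dI, g$first_right),
               num, tolerance = 1e-5)
})

test_that("replicate fits recover the generating parameters", {
  set.seed(6)
  est <- t(replicate(50, {
    cfg <- population_config(n_subjects = 1, games_per_cell = 200,
                             seed = NULL)
    tr <- gen_horizon_games(make_subject(10, 8), cfg)
    g <- games_from_trials(tr)
    f <- fit_horizon(g[g$horizon == 1, ], 1)
    c(f$info_bonus, f$side_bias, f$noise)
  }))
  med <- apply(est, 2, median)
  expect_lt(abs(med[1] - 10), 3)
  expect_lt(abs(med[2] - 0), 3)
  expect_lt(abs(med[3] - 8), 3)
})

test_that("fits are relabel-equivariant and flag degenerate choice sets", {
  g <- one_horizon_games(ib = 8, noise = 10, n_per_cond = 100, seed = 7,
                         bias = 4)
  set.seed(100)
  f1 <- fit_horizon(g, 1)
  g2 <- g
  g2$dR <- -g$dR; g2$dI <- -g$dI; g2$first_right <- 1L - g$first_right
  set.seed(100)
  f2 <- fit_horizon(g2, 1)
  expect_equal(f1$info_bonus, f2$info_bonus, tolerance = 1e-3)
  expect_equal(f1$side_bias, -f2$side_bias, tolerance = 1e-3)
  expect_equal(f1$noise, f2$noise, tolerance = 1e-3)
  # all-identical choices sit on a likelihood boundary
  g3 <- g; g3$first_right <- 1L
  expect_warning(f3 <- fit_horizon(g3[1:30, ], 1), NA)
  expect_true(f3$boundary)
})

test_that("model-based and model-free exploration measures cohere", {
  # the horizon change in the fitted information bonus must track measured
  # directed exploration, and the change in (log) decision noise must track
  # measured random exploration. The info-bonus correlation is capped near
  # 0.65 even at perfect recovery: heterogeneous decision noise flattens the
  # bonus-to-probability mapping differently per subject, so thresholds are
  # set ~3 SE below the values the generator's population actually attains
  # (~0.65 and ~0.74).
  cfg <- population_config(n_subjects = 300, games_per_cell = 100, seed = 8)
  sim <- simulate_study(cfg)
  g <- games_from_trials(sim$trials)
  m <- horizon_metrics(g)
  set.seed(8)
  f <- fit_horizon_all(g)
  wide <- merge(f[f$horizon == 1, c("subject_id", "info_bonus", "noise")],
                f[f$horizon == 6, c("subject_id", "info_bonus", "noise")],
                by = "subject_id", suffixes = c("_h1", "_h6"))
  wide <- merge(wide, m, by = "subject_id")
  expect_gt(cor(wide$info_bonus_h6 - wide$info_bonus_h1, wide$directed),
            0.55)
  expect_gt(cor(log(wide$noise_h6) - log(wide$noise_h1), wide$random), 0.6)
})
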