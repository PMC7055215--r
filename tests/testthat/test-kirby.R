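test_that("packaged instrument satisfies its structural invariants", {
  inst <- kirby_instrument()
  expect_equal(nrow(inst), 27)
  expect_true(all(table(inst$bin) == 9))
  expect_true(all(inst$delayed > inst$immediate))
  # items the source article quotes verbatim
  expect_equal(unlist(inst[inst$index == 2,
                           c("immediate", "delayed", "delay_days")]),
               c(immediate = 55, delayed = 75, delay_days = 61))
  expect_equal(unlist(inst[inst$index == 7,
                           c("immediate", "delayed", "delay_days")]),
               c(immediate = 15, delayed = 35, delay_days = 13))
  expect_equal(unlist(inst[inst$index == 11,
                           c("immediate", "delayed", "delay_days")]),
               c(immediate = 11, delayed = 30, delay_days = 7))
  expect_equal(unlist(inst[inst$index == 19,
                           c("immediate", "delayed", "delay_days")]),
               c(immediate = 33, delayed = 80, delay_days = 14))
  expect_error(validate_instrument(inst[-3, ]), "1..27")
  bad <- inst; bad$immediate[1] <- 5
  expect_error(validate_instrument(bad), "\\[11, 80\\]")
})

test_that("hyperbolic value matches worked examples and limits", {
  expect_equal(hyperbolic_value(75, 61, 0.00596125), 55, tolerance = 1e-6)
  expect_equal(hyperbolic_value(35, 13, 0.102564103), 15, tolerance = 1e-6)
  expect_equal(hyperbolic_value(100, 0, 0.5), 100)
  expect_equal(hyperbolic_value(100, 30, 0), 100)
  # decreasing in k and in D
  expect_lt(hyperbolic_value(80, 30, 0.1), hyperbolic_value(80, 30, 0.05))
  expect_lt(hyperbolic_value(80, 60, 0.1), hyperbolic_value(80, 30, 0.1))
  expect_error(hyperbolic_value(-1, 10, 0.1), "positive")
  expect_error(hyperbolic_value(10, -1, 0.1), "nonnegative")
  expect_error(hyperbolic_value(10, 1, -0.1), "nonnegative")
})

test_that("indifference points solve the discounting equation", {
  inst <- kirby_instrument()
  ks <- indifference_k(inst)
  expect_lt(abs(ks[inst$index == 2] - 0.00596125), 5e-9)
  expect_lt(abs(ks[inst$index == 7] - 0.102564103), 1e-9)
  # the defining property: discounted delayed value equals the immediate
  expect_equal(hyperbolic_value(inst$delayed, inst$delay_days, ks),
               inst$immediate, tolerance = 1e-12)
  expect_equal(indifference_k(data.frame(immediate = 40, delayed = 40,
                                         delay_days = 10)), 0)
})

test_that("extreme responders score at the ladder endpoints", {
  s_later <- score_subject(rep("later", 27))
  expect_equal(s_later$n_today, 0)
  expect_equal(unlist(s_later[c("k_overall", "k_small", "k_medium",
                                "k_large", "k_geomean")]),
               c(k_overall = K_FLOOR, k_small = K_FLOOR, k_medium = K_FLOOR,
                 k_large = K_FLOOR, k_geomean = K_FLOOR))
  expect_equal(s_later$consistency_overall, 1)
  s_today <- score_subject(rep("today", 27))
  expect_equal(s_today$n_today, 27)
  expect_equal(s_today$prop_today, 1)
  expect_equal(s_today$k_overall, K_CEIL)
  expect_equal(s_today$k_geomean, K_CEIL)
  expect_equal(s_today$consistency_overall, 1)
})

test_that("deterministic responders are scored inside the true-k gap", {
  inst <- kirby_instrument()
  ks <- sort(unique(indifference_k(inst)))
  for (true_k in c(0.0008, 0.02, 0.11)) {
    s <- score_subject(det_profile(true_k))
    below <- max(ks[ks < true_k]); above <- min(ks[ks > true_k])
    expect_gt(s$k_overall, below)
    expect_lt(s$k_overall, above)
    expect_equal(s$consistency_overall, 1)
    # oracle: no rate on a dense log-spaced grid does better
    grid <- exp(seq(log(K_FLOOR), log(K_CEIL), length.out = 10000))
    best_grid <- max(vapply(grid, grid_consistency, numeric(1),
                            items = inst, choices = det_profile(true_k)))
    expect_gte(s$consistency_overall, best_grid)
  }
})

test_that("assigned rate attains the grid-maximal consistency for noisy profiles", {
  inst <- kirby_instrument()
  # span the grid from below the lowest item indifference point (the ladder
  # floor denotes a rate below every item) up to the ceiling
  lo <- 0.9 * min(indifference_k(inst))
  grid <- exp(seq(log(lo), log(K_CEIL), length.out = 10000))
  set.seed(42)
  for (rep in 1:5) {
    choices <- sample(c("today", "later"), 27, replace = TRUE)
    for (bin in list(inst, inst[inst$bin == "small", ])) {
      ch <- choices[seq_len(nrow(bin))]
      sb <- score_bin(bin, ch)
      best_grid <- max(vapply(grid, grid_consistency, numeric(1),
                              items = bin, choices = ch))
      expect_gte(sb$consistency + 1e-12, best_grid)
    }
  }
})

test_that("scoring is invariant to item presentation order", {
  inst <- kirby_instrument()
  ch <- det_profile(0.02)
  set.seed(7)
  perm <- sample(27)
  a <- score_bin(inst, ch)
  b <- score_bin(inst[perm, ], ch[perm])
  expect_equal(a, b)
})

test_that("flipping one response toward 'today' never lowers a consistent k", {
  inst <- kirby_instrument()
  for (true_k in c(0.001, 0.02, 0.15)) {
    ch <- det_profile(true_k)
    k0 <- score_subject(ch)$k_overall
    for (i in which(ch == "later")) {
      ch2 <- ch; ch2[i] <- "today"
      expect_gte(score_subject(ch2)$k_overall, k0 - 1e-12)
    }
  }
})

test_that("geometric-mean k ties the three bin rates together", {
  set.seed(11)
  ch <- sample(c("today", "later"), 27, replace = TRUE)
  s <- score_subject(ch)
  expect_equal(s$k_geomean,
               exp(mean(log(c(s$k_small, s$k_medium, s$k_large)))),
               tolerance = 1e-12)
  expect_equal(s$prop_today, s$n_today / 27)
})

test_that("partial profiles are rejected by default and flagged when allowed", {
  resp <- data.frame(subject_id = "p1", item_index = c(1:10, 12:27),
                     choice = "later")
  expect_error(score_kirby(resp), "missing item\\(s\\): 11")
  flagged <- score_kirby(resp, partial = "flag")
  expect_true(flagged$partial)
  expect_equal(flagged$n_answered, 26)
  full <- data.frame(subject_id = "p2", item_index = 1:27, choice = "today")
  expect_false(score_kirby(full)$partial)
})

test_that("number of today choices tracks the fitted discount rate", {
  # noisy responders at the generator's default choice noise
  set.seed(21)
  cfg <- population_config(n_subjects = 300, games_per_cell = 4, seed = 21)
  pop <- gen_population(cfg)
  resp <- gen_kirby_responses(pop, choice_noise = cfg$kirby_choice_noise)
  sc <- score_kirby(resp)
  expect_gte(cor(sc$prop_today, log(sc$k_overall)), 0.89)
  # and n_today is nondecreasing in true k for deterministic responders
  ks <- exp(seq(log(K_FLOOR), log(K_CEIL), length.out = 60))
  n_today <- vapply(ks, function(k) sum(det_profile(k) == "today"),
                    numeric(1))
  expect_true(all(diff(n_today) >= 0))
})
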