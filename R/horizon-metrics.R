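#' Summarize a Horizon Task trial log into per-game records
#'
#' Collapses a long trial log (one row per trial) into one row per game,
#' carrying the quantities the analyses need: forced-trial counts and
#' observed means per side, the reward-difference and information-difference
#' predictors of the first free choice, and the first free choice itself.
#'
#' Games with no free choice are dropped (a message reports how many).
#'
#' @param trials data.frame with columns `subject_id`, `game_id`, `horizon`
#'   (1 or 6), `info_condition` (`"unequal_13"` or `"equal_22"`),
#'   `trial_index` (1-based; trial 5 is the first free choice), `forced`
#'   (1 = forced, 0 = free), `side` (`"left"`/`"right"`), `reward`, `rt`
#'   (seconds; `NA` on forced trials), `mean_left`, `mean_right`
#'   (generative means).
#' @return data.frame, one row per game: identifiers and condition columns
#'   plus `n_forced_left`, `n_forced_right`, `fmean_left`, `fmean_right`
#'   (observed forced means), `dR` (observed forced mean, right minus left),
#'   `dI` (+1 if right is the once-played side, -1 if left, 0 in
#'   `equal_22`), `first_side`, `first_right` (0/1), `first_rt`, `n_free`.
#' @export
games_from_trials <- function(trials) {
  need <- c("subject_id", "game_id", "horizon", "info_condition",
            "trial_index", "forced", "side", "reward", "rt",
            "mean_left", "mean_right")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    stop("trial log is missing columns: ", paste(miss, collapse = ", "))
  dt <- data.table::as.data.table(trials)
  bad <- dt[!side %in% c("left", "right"), which = TRUE]
  if (length(bad))
    stop("invalid side value at trial-log row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  forced <- dt[forced == 1,
    .(n_forced = .N,
      n_forced_left = sum(side == "left"),
      n_forced_right = sum(side == "right"),
      fmean_left = mean(reward[side == "left"]),
      fmean_right = mean(reward[side == "right"]),
      horizon = horizon[1], info_condition = info_condition[1],
      mean_left = mean_left[1], mean_right = mean_right[1]),
    by = .(subject_id, game_id)]
  if (any(forced$n_forced != 4L))
    stop("each game must have exactly 4 forced trials")
  okcnt <- with(forced, ifelse(info_condition == "equal_22",
                               n_forced_left == 2L,
                               pmin(n_forced_left, n_forced_right) == 1L))
  if (!all(okcnt))
    stop("forced-side counts must be {2,2} in equal_22 and {1,3} in unequal_13")
  free <- dt[forced == 0][order(trial_index),
    .(first_side = side[1], first_right = as.integer(side[1] == "right"),
      first_reward = reward[1], first_rt = rt[1], n_free = .N),
    by = .(subject_id, game_id)]
  games <- merge(forced, free, by = c("subject_id", "game_id"),
                 all.x = TRUE)
  n_drop <- sum(is.na(games$first_side))
  if (n_drop > 0) {
    message("dropping ", n_drop, " game(s) with no free choice")
    games <- games[!is.na(games$first_side)]
  }
  games[, dR := fmean_right - fmean_left]
  games[, dI := ifelse(info_condition == "equal_22", 0L,
                       ifelse(n_forced_right == 1L, 1L, -1L))]
  out <- as.data.frame(games)
  out[order(out$subject_id, out$game_id), , drop = FALSE]
}

#' Classify the first free choice of each game
#'
#' Flags, per game, whether the first free choice was the more informative
#' option (defined only in the `unequal_13` condition: the side played once
#' among the forced trials), whether it was the option with the lower
#' generative mean, and whether it was correct (the higher generative mean).
#' Games whose generative means are equal have `chose_low_mean` and
#' `correct` undefined (`NA`) and are excluded from those denominators.
#'
#' @param games per-game data.frame from [games_from_trials()].
#' @return `games` with columns `chose_high_info`, `chose_low_mean`,
#'   `correct` (logical, `NA` where undefined) and `rt` appended.
#' @export
classify_first_free <- function(games) {
  right <- games$first_right == 1L
  high_info_right <- games$dI == 1L
  chose_high_info <- ifelse(games$info_condition == "unequal_13",
                            right == high_info_right, NA)
  lower_right <- games$mean_right < games$mean_left
  tie <- games$mean_right == games$mean_left
  chose_low_mean <- ifelse(tie, NA, right == lower_right)
  games$chose_high_info <- chose_high_info
  games$chose_low_mean <- chose_low_mean
  games$correct <- ifelse(tie, NA, right == !lower_right)
  games$rt <- games$first_rt
  games
}

# means over a logical vector that may be empty / all-NA -> NA with warning
.cell_mean <- function(x, what, id) {
  x <- x[!is.na(x)]
  if (!length(x)) {
    warning("subject ", id, ": no games for ", what, "; value set to NA",
            call. = FALSE)
    return(NA_real_)
  }
  mean(x)
}

#' Model-free Horizon Task measures for one subject
#'
#' Computes, per horizon, the probability of choosing the more informative
#' option in `unequal_13` games (p(high info)), the probability of choosing
#' the lower generative-mean option in `equal_22` games (p(low mean)),
#' accuracy (choosing the higher generative-mean option, all games), and the
#' mean first-free-choice reaction time. Directed exploration is the
#' horizon-6 minus horizon-1 change in p(high info); random exploration the
#' change in p(low mean).
#'
#' @param games per-game data.frame for one subject
#'   (from [games_from_trials()]).
#' @return one-row data.frame: `p_high_info_h1`, `p_high_info_h6`,
#'   `p_low_mean_h1`, `p_low_mean_h6`, `accuracy_h1`, `accuracy_h6`,
#'   `rt_h1`, `rt_h6`, `directed`, `random`, and the four
#'   horizon x condition game counts.
#' @export
subject_metrics <- function(games) {
  g <- classify_first_free(games)
  id <- if (nrow(g)) g$subject_id[1] else "<empty>"
  cell <- function(h, cond) g[g$horizon == h & g$info_condition == cond, ]
  m <- list()
  for (h in c(1, 6)) {
    hh <- paste0("h", h)
    uneq <- cell(h, "unequal_13"); eq <- cell(h, "equal_22")
    m[[paste0("p_high_info_", hh)]] <-
      .cell_mean(uneq$chose_high_info, paste0("p(high info) ", hh), id)
    m[[paste0("p_low_mean_", hh)]] <-
      .cell_mean(eq$chose_low_mean, paste0("p(low mean) ", hh), id)
    sub <- g[g$horizon == h, ]
    m[[paste0("accuracy_", hh)]] <-
      .cell_mean(sub$correct, paste0("accuracy ", hh), id)
    m[[paste0("rt_", hh)]] <- .cell_mean(sub$rt, paste0("rt ", hh), id)
    m[[paste0("n_unequal_", hh)]] <- nrow(uneq)
    m[[paste0("n_equal_", hh)]] <- nrow(eq)
  }
  m$directed <- m$p_high_info_h6 - m$p_high_info_h1
  m$random <- m$p_low_mean_h6 - m$p_low_mean_h1
  as.data.frame(m)
}

#' Model-free Horizon Task measures for every subject
#'
#' @param x either a per-game data.frame from [games_from_trials()] or a raw
#'   trial log (detected by the presence of a `trial_index` column).
#' @return data.frame with one row per subject: `subject_id` plus the
#'   [subject_metrics()] columns.
#' @examples
#' \donttest{
#' cfg <- population_config(n_subjects = 4, games_per_cell = 8, seed = 1)
#' sim <- simulate_study(cfg)
#' head(horizon_metrics(sim$trials))
#' }
#' @export
horizon_metrics <- function(x) {
  games <- if ("trial_index" %in% names(x)) games_from_trials(x) else x
  ids <- unique(games$subject_id)
  idx <- split(seq_len(nrow(games)), factor(games$subject_id, levels = ids))
  rows <- lapply(ids, function(id) {
    cbind(subject_id = id,
          subject_metrics(games[idx[[as.character(id)]], , drop = FALSE]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
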