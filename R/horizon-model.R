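#' Logistic first-free-choice probability
#'
#' Probability that the first free choice is the right-hand option under the
#' logistic choice model
#' `p(right) = 1 / (1 + exp(-(dR + info_bonus * dI + side_bias) / noise))`,
#' where `dR` is the observed mean forced reward (right minus left), `dI`
#' codes the information asymmetry (+1 if the right option was played once,
#' -1 if the left, 0 in the equal condition), `info_bonus` is the value (in
#' reward points) added to the less-sampled option, `side_bias` a constant
#' preference for the right side, and `noise` the decision temperature.
#'
#' @param params list or one-row data.frame with `info_bonus`, `side_bias`,
#'   `noise` (points; `noise > 0`).
#' @param dR numeric vector of reward differences (points, right - left).
#' @param dI integer vector in \{-1, 0, 1\}.
#' @return probability/ies of choosing right, in (0, 1).
#' @examples
#' choice_prob(list(info_bonus = 0, side_bias = 0, noise = 8), dR = 0, dI = 0)
#' @export
choice_prob <- function(params, dR, dI) {
  if (params$noise <= 0) stop("noise must be positive")
  plogis((dR + params$info_bonus * dI + params$side_bias) / params$noise)
}

#' Negative log-likelihood of first free choices
#'
#' Bernoulli negative log-likelihood of the observed first free choices
#' under [choice_prob()]; additive over games.
#'
#' @param params as in [choice_prob()].
#' @param games per-game data.frame (from [games_from_trials()]) with
#'   columns `dR`, `dI`, `first_right`.
#' @return nonnegative scalar; lower is better.
#' @export
neg_log_lik <- function(params, games) {
  .nll(c(params$info_bonus, params$side_bias, log(params$noise)),
       games$dR, games$dI, games$first_right)
}

# par = (info_bonus, side_bias, log noise)
.nll <- function(par, dR, dI, y) {
  z <- (dR + par[1] * dI + par[2]) / exp(par[3])
  # -[y log p + (1-y) log(1-p)] in a numerically stable form
  sum(log1p(exp(-abs(z))) + pmax(z, 0) - y * z)
}

.nll_grad <- function(par, dR, dI, y) {
  sigma <- exp(par[3])
  z <- (dR + par[1] * dI + par[2]) / sigma
  r <- plogis(z) - y
  c(sum(r * dI) / sigma, sum(r) / sigma, -sum(r * z))
}

#' Parameter bounds for the logistic model fit
#'
#' Box constraints used by [fit_horizon()]: information bonus and side bias
#' in [-80, 80] points, decision noise in [0.1, 200] points (optimized on
#' the log scale).
#' @return list with `lower` and `upper` vectors over
#'   (info_bonus, side_bias, log noise).
#' @export
horizon_fit_bounds <- function() {
  list(lower = c(-80, -80, log(0.1)), upper = c(80, 80, log(200)))
}

#' Fit the logistic choice model for one subject and horizon
#'
#' Maximum-likelihood fit of (information bonus, side bias, decision noise)
#' to the first free choices of one horizon, pooling both information
#' conditions (`dI = 0` in `equal_22`). Uses bounded L-BFGS-B with analytic
#' gradients from multiple Latin-hypercube starting points; the best
#' negative log-likelihood wins, with near-ties (within 1e-6) resolved
#' toward the smallest `|info_bonus|`.
#'
#' @param games per-game data.frame (one subject, or any set of games to be
#'   pooled) with `dR`, `dI`, `first_right`, `horizon`.
#' @param horizon 1 or 6; games from the other horizon are ignored.
#' @param n_starts number of multi-start initializations (default 10).
#' @return one-row data.frame: `horizon`, `info_bonus`, `side_bias`, `noise`,
#'   `nll`, `n_games`, `converged` (optimizer convergence at the winning
#'   start), `boundary` (TRUE when all observed choices were identical, so
#'   the parameters sit on a likelihood boundary).
#' @export
fit_horizon <- function(games, horizon, n_starts = 10) {
  g <- games[games$horizon == horizon, , drop = FALSE]
  n <- nrow(g)
  if (n == 0) stop("no games at horizon ", horizon)
  if (n < 20)
    warning("only ", n, " first free choices at horizon ", horizon,
            "; estimates will be unstable", call. = FALSE)
  y <- g$first_right
  boundary <- length(unique(y)) == 1L
  b <- horizon_fit_bounds()
  u <- lhs::randomLHS(n_starts, 3)
  starts <- sweep(sweep(u, 2, b$upper - b$lower, "*"), 2, b$lower, "+")
  # include one neutral start at (0, 0, log SD of task payouts)
  starts[1, ] <- c(0, 0, log(8))
  fits <- lapply(seq_len(n_starts), function(i) {
    optim(starts[i, ], fn = .nll, gr = .nll_grad,
          dR = g$dR, dI = g$dI, y = y,
          method = "L-BFGS-B", lower = b$lower, upper = b$upper,
          control = list(maxit = 500))
  })
  nlls <- vapply(fits, `[[`, numeric(1), "value")
  near <- which(nlls <= min(nlls) + 1e-6)
  win <- near[which.min(abs(vapply(fits[near], function(f) f$par[1],
                                   numeric(1))))]
  best <- fits[[win]]
  data.frame(horizon = horizon,
             info_bonus = best$par[1],
             side_bias = best$par[2],
             noise = exp(best$par[3]),
             nll = best$value,
             n_games = n,
             converged = best$convergence == 0,
             boundary = boundary)
}

#' Fit the logistic model for every subject and both horizons
#'
#' @param x per-game data.frame from [games_from_trials()], or a raw trial
#'   log (detected by a `trial_index` column).
#' @param n_starts multi-start count per fit, see [fit_horizon()].
#' @return data.frame with one row per subject x horizon:
#'   `subject_id`, `horizon`, `info_bonus`, `side_bias`, `noise`, `nll`,
#'   `n_games`, `converged`, `boundary`.
#' @examples
#' \donttest{
#' cfg <- population_config(n_subjects = 2, games_per_cell = 16, seed = 1)
#' sim <- simulate_study(cfg)
#' fit_horizon_all(sim$trials)
#' }
#' @export
fit_horizon_all <- function(x, n_starts = 10) {
  games <- if ("trial_index" %in% names(x)) games_from_trials(x) else x
  ids <- unique(games$subject_id)
  idx <- split(seq_len(nrow(games)), factor(games$subject_id, levels = ids))
  rows <- lapply(ids, function(id) {
    g <- games[idx[[as.character(id)]], , drop = FALSE]
    do.call(rbind, lapply(c(1, 6), function(h) {
      cbind(subject_id = id, fit_horizon(g, h, n_starts = n_starts))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
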