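#' Scoring bounds for the discount-rate ladder
#'
#' Endpoints of the instrument's nominal discount-rate ladder (day^-1).
#' A fully patient responder (all "later") is assigned `K_FLOOR`; a fully
#' impulsive responder (all "today") is assigned `K_CEIL`.
#' @export
K_FLOOR <- 0.00016

#' @rdname K_FLOOR
#' @export
K_CEIL <- 0.25

#' Hyperbolic present value of a delayed reward
#'
#' Computes `V = A / (1 + k * D)`: the present (subjective) value of a
#' reward of `A` dollars arriving after `D` days under hyperbolic
#' discounting at rate `k` per day.
#'
#' @param A delayed amount (dollars), > 0. Vectorized.
#' @param D delay in days, >= 0.
#' @param k discount rate (1/day), >= 0.
#' @return Present value in dollars; equals `A` when `D = 0` or `k = 0`.
#' @examples
#' hyperbolic_value(75, 61, 0.00596125)  # ~55
#' @export
hyperbolic_value <- function(A, D, k) {
  if (any(A <= 0)) stop("delayed amount A must be positive")
  if (any(D < 0)) stop("delay D must be nonnegative")
  if (any(k < 0)) stop("discount rate k must be nonnegative")
  A / (1 + k * D)
}

#' Indifference-point discount rate of an item
#'
#' The discount rate at which the immediate and delayed options of a
#' questionnaire item have equal subjective value under hyperbolic
#' discounting: `k = (delayed/immediate - 1) / delay`.
#'
#' @param item one row of an instrument data.frame (or a data.frame of
#'   items; the computation is vectorized over rows).
#' @return Indifference rate(s) in day^-1.
#' @examples
#' indifference_k(data.frame(immediate = 55, delayed = 75, delay_days = 61))
#' @export
indifference_k <- function(item) {
  if (any(item$immediate <= 0)) stop("immediate amount must be positive")
  if (any(item$delay_days <= 0)) stop("delay must be positive")
  (item$delayed / item$immediate - 1) / item$delay_days
}

# Candidate discount rates for a set of items: geometric means of adjacent
# distinct sorted indifference points, plus the floor and ceiling. The floor
# candidate predicts "later" everywhere and the ceiling "today" everywhere
# (they denote rates below/above every item, not literal comparisons, since
# the nominal ladder endpoints straddle the extreme item values). Returns a
# list with candidate values, their prediction matrix (TRUE = today), and
# bracketing intervals.
kirby_candidates <- function(item_k) {
  u <- sort(unique(item_k))
  # collapse values that differ only by floating-point noise (several items
  # share a mathematical indifference point, e.g. 1/6318 twice)
  u <- u[c(TRUE, diff(log(u)) > 1e-9)]
  m <- length(u)
  mids <- if (m > 1) sqrt(u[-m] * u[-1]) else numeric(0)
  cand <- c(K_FLOOR, mids, K_CEIL)
  lo <- c(K_FLOOR, u[-m], u[m])
  hi <- c(u[1], u[-1], K_CEIL)
  # prediction: today iff candidate k exceeds the item's indifference k;
  # equality (within fp tolerance) is consistent with either choice -> NA
  pred <- outer(cand, item_k, ">")
  pred[1, ] <- FALSE
  pred[length(cand), ] <- TRUE
  tie <- outer(cand, item_k, function(a, b) abs(a - b) <= 1e-12 * pmax(a, b))
  tie[c(1, length(cand)), ] <- FALSE
  pred[tie] <- NA
  list(k = cand, pred = pred, lo = lo, hi = hi)
}

#' Score one magnitude bin (or the full instrument) of responses
#'
#' Assigns the discount rate that maximizes consistency with the observed
#' choice pattern. Candidate rates are the geometric means of adjacent
#' distinct item indifference points, plus the ladder floor and ceiling.
#' An item whose indifference point equals the candidate is consistent with
#' either choice. Consistency ties are resolved by the geometric mean of all
#' maximizing candidates.
#'
#' @param items data.frame of instrument items (one bin, or all 27).
#' @param choices character vector aligned with `items` rows, each
#'   `"today"` or `"later"`.
#' @return A list with `k` (assigned rate, day^-1), `consistency` (maximum
#'   fraction of items consistent), and `k_low`, `k_high` (the bracketing
#'   interval of item indifference points around the assigned rate).
#' @examples
#' inst <- kirby_instrument()
#' small <- inst[inst$bin == "small", ]
#' score_bin(small, rep("later", 9))  # fully patient: K_FLOOR
#' @export
score_bin <- function(items, choices) {
  if (length(choices) != nrow(items))
    stop("need one choice per item")
  if (anyNA(choices) || !all(choices %in% c("today", "later")))
    stop("choices must be 'today' or 'later'")
  item_k <- indifference_k(items)
  cc <- kirby_candidates(item_k)
  today <- choices == "today"
  # consistency: predicted NA (tie) always matches
  match_mat <- sweep(cc$pred, 2, today, "==")
  match_mat[is.na(match_mat)] <- TRUE
  cons <- rowMeans(match_mat)
  best <- max(cons)
  idx <- which(cons >= best - 1e-12)
  k <- exp(mean(log(cc$k[idx])))
  list(k = k, consistency = best,
       k_low = min(cc$lo[idx]), k_high = max(cc$hi[idx]))
}

#' Score one subject's questionnaire responses
#'
#' Computes the six temporal-discounting measures for a single subject:
#' overall discount rate from all 27 items, rates for the small, medium and
#' large magnitude bins, the geometric mean of the three bin rates, and the
#' number (and proportion) of "today" choices. Per-bin consistency values
#' and bracketing intervals are included.
#'
#' @param responses named access to the subject's choices: either a
#'   data.frame with columns `item_index` and `choice`, or a character
#'   vector of length 27 ordered by item index.
#' @param instrument instrument data.frame; defaults to the packaged one.
#' @param partial `"error"` (default) rejects profiles with missing items;
#'   `"flag"` scores the answered items only and sets `partial = TRUE`.
#' @return A one-row data.frame with columns `k_overall`, `k_small`,
#'   `k_medium`, `k_large`, `k_geomean`, `n_today`, `prop_today`,
#'   `consistency_overall/_small/_medium/_large`,
#'   `k_overall_low`, `k_overall_high`, `n_answered`, `partial`.
#' @export
score_subject <- function(responses, instrument = kirby_instrument(),
                          partial = c("error", "flag")) {
  partial <- match.arg(partial)
  if (is.data.frame(responses)) {
    ch <- rep(NA_character_, 27)
    ch[responses$item_index] <- as.character(responses$choice)
  } else {
    ch <- as.character(responses)
    if (length(ch) != 27) stop("need 27 choices when passing a vector")
  }
  missing_idx <- setdiff(instrument$index, which(!is.na(ch)))
  if (length(missing_idx) && partial == "error")
    stop("profile incomplete; missing item(s): ",
         paste(sort(missing_idx), collapse = ", "))
  keep <- instrument$index[!is.na(ch[instrument$index])]
  inst <- instrument[instrument$index %in% keep, ]
  ch_kept <- ch[inst$index]

  overall <- score_bin(inst, ch_kept)
  bins <- lapply(c(small = "small", medium = "medium", large = "large"),
                 function(b) {
                   sel <- inst$bin == b
                   score_bin(inst[sel, ], ch_kept[sel])
                 })
  k_geomean <- exp(mean(log(c(bins$small$k, bins$medium$k, bins$large$k))))
  n_today <- sum(ch_kept == "today")
  data.frame(
    k_overall = overall$k,
    k_small = bins$small$k, k_medium = bins$medium$k, k_large = bins$large$k,
    k_geomean = k_geomean,
    n_today = n_today,
    prop_today = n_today / length(ch_kept),
    consistency_overall = overall$consistency,
    consistency_small = bins$small$consistency,
    consistency_medium = bins$medium$consistency,
    consistency_large = bins$large$consistency,
    k_overall_low = overall$k_low,
    k_overall_high = overall$k_high,
    n_answered = length(ch_kept),
    partial = length(missing_idx) > 0
  )
}

#' Score a table of questionnaire responses
#'
#' Scores every subject in a long response table (one row per
#' subject x item).
#'
#' @param responses data.frame with columns `subject_id`, `item_index`,
#'   `choice` (`"today"`/`"later"`).
#' @param instrument instrument data.frame; defaults to the packaged one.
#' @param partial see [score_subject()].
#' @return data.frame with one row per subject: `subject_id` followed by the
#'   [score_subject()] columns.
#' @examples
#' resp <- data.frame(subject_id = "s1", item_index = 1:27,
#'                    choice = rep("later", 27))
#' score_kirby(resp)$k_overall  # K_FLOOR
#' @export
score_kirby <- function(responses, instrument = kirby_instrument(),
                        partial = c("error", "flag")) {
  partial <- match.arg(partial)
  need <- c("subject_id", "item_index", "choice")
  miss <- setdiff(need, names(responses))
  if (length(miss))
    stop("responses table is missing columns: ", paste(miss, collapse = ", "))
  ids <- unique(responses$subject_id)
  rows <- lapply(ids, function(id) {
    one <- responses[responses$subject_id == id, ]
    if (anyDuplicated(one$item_index))
      stop("duplicate item responses for subject ", id)
    cbind(subject_id = id,
          score_subject(one, instrument = instrument, partial = partial))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
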