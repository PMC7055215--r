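# 32-bit FNV-1a over the deparsed object; a short stable fingerprint for
# recording which configuration produced an output file
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    # xor the low octet (bitwXor cannot take values beyond 2^31)
    low <- h %% 256
    h <- h - low + bitwXor(low, b %% 256)
    # 32-bit modular multiply in two 16-bit halves (doubles lose precision
    # above 2^53, so h * prime cannot be taken directly)
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * prime + ((hi * prime) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Write a table as CSV with a provenance header
#'
#' Writes a data.frame as plain CSV preceded by `#`-comment lines recording
#' the package version, the seed, and a fingerprint of the generating
#' configuration, so every output file documents its own provenance.
#'
#' @param df data.frame to write.
#' @param path output file path.
#' @param seed seed recorded in the header (`NA` if none applies).
#' @param config optional configuration object; its fingerprint is recorded.
#' @return `path`, invisibly.
#' @export
write_output_csv <- function(df, path, seed = NA, config = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    sprintf("# kirbyhorizon %s", as.character(packageVersion("kirbyhorizon"))),
    sprintf("# seed: %s", as.character(seed)),
    sprintf("# config_hash: %s",
            if (is.null(config)) "none" else config_hash(config))
  ), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a CSV written by this package
#'
#' Reads a plain CSV, skipping `#`-comment (provenance) lines.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_output_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read a questionnaire response table
#'
#' Expects columns `subject_id`, `item_index`, `choice`
#' (`"today"`/`"later"`); reports offending row numbers on schema
#' violations.
#'
#' @param path CSV file path.
#' @return validated long response data.frame.
#' @export
read_responses <- function(path) {
  resp <- read_output_csv(path)
  need <- c("subject_id", "item_index", "choice")
  miss <- setdiff(need, names(resp))
  if (length(miss))
    stop("response file missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(!resp$choice %in% c("today", "later"))
  if (length(bad))
    stop("invalid choice value at row(s): ",
         paste(head(bad, 5), collapse = ", "))
  bad <- which(!(resp$item_index %in% 1:27))
  if (length(bad))
    stop("item_index out of 1..27 at row(s): ",
         paste(head(bad, 5), collapse = ", "))
  resp
}

#' Read a Horizon Task trial log
#'
#' Expects the [games_from_trials()] schema; reports offending row numbers
#' on schema violations.
#'
#' @param path CSV file path.
#' @return validated long trial-log data.frame.
#' @export
read_trials <- function(path) {
  trials <- read_output_csv(path)
  need <- c("subject_id", "game_id", "horizon", "info_condition",
            "trial_index", "forced", "side", "reward", "rt",
            "mean_left", "mean_right")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    stop("trial log missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(!trials$horizon %in% c(1, 6))
  if (length(bad))
    stop("horizon must be 1 or 6; bad row(s): ",
         paste(head(bad, 5), collapse = ", "))
  bad <- which(!trials$info_condition %in% c("unequal_13", "equal_22"))
  if (length(bad))
    stop("invalid info_condition at row(s): ",
         paste(head(bad, 5), collapse = ", "))
  bad <- which(!trials$side %in% c("left", "right"))
  if (length(bad))
    stop("invalid side at row(s): ", paste(head(bad, 5), collapse = ", "))
  trials
}
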