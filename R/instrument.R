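#' The 27-item monetary choice questionnaire
#'
#' Returns the packaged 27-item delay-discounting instrument. Each item asks
#' for a preference between a smaller immediate reward and a larger delayed
#' reward; items are split into three 9-item magnitude bins by the size of
#' the delayed reward (small $25--35, medium $50--60, large $75--85).
#'
#' @return A data.frame with columns `index` (1--27), `immediate` (dollars),
#'   `delayed` (dollars), `delay_days`, and `bin`
#'   (one of `"small"`, `"medium"`, `"large"`).
#' @examples
#' inst <- kirby_instrument()
#' table(inst$bin)
#' @export
kirby_instrument <- function() {
  inst <- data.frame(
    index     = 1:27,
    immediate = c(54, 55, 19, 31, 14, 47, 15, 25, 78,
                  40, 11, 67, 34, 27, 69, 49, 80, 24,
                  33, 28, 34, 25, 41, 54, 54, 22, 20),
    delayed   = c(55, 75, 25, 85, 25, 50, 35, 60, 80,
                  55, 30, 75, 35, 50, 85, 60, 85, 35,
                  80, 30, 50, 30, 75, 60, 80, 25, 55),
    delay_days = c(117, 61, 53, 7, 19, 160, 13, 14, 162,
                   62, 7, 119, 186, 21, 91, 89, 157, 29,
                   14, 179, 30, 80, 20, 111, 30, 136, 7),
    stringsAsFactors = FALSE
  )
  inst$bin <- c("medium", "large", "small", "large", "small", "medium",
                "small", "medium", "large", "medium", "small", "large",
                "small", "medium", "large", "medium", "large", "small",
                "large", "small", "medium", "small", "large", "medium",
                "large", "small", "medium")
  validate_instrument(inst)
  inst
}

#' Validate an instrument table
#'
#' Checks the structural invariants of a 27-item monetary choice instrument:
#' column types, positive amounts with `delayed > immediate`, positive
#' delays, the published value ranges (immediate $11--80, delayed $25--85,
#' delay 7--186 days) and exactly nine items per magnitude bin.
#'
#' @param instrument data.frame as returned by [kirby_instrument()].
#' @return The instrument, invisibly, if valid; otherwise an error.
#' @export
validate_instrument <- function(instrument) {
  needed <- c("index", "immediate", "delayed", "delay_days", "bin")
  miss <- setdiff(needed, names(instrument))
  if (length(miss))
    stop("instrument is missing columns: ", paste(miss, collapse = ", "))
  if (!identical(sort(as.integer(instrument$index)), 1:27))
    stop("instrument must contain items indexed 1..27 exactly once")
  with(instrument, {
    if (any(!(delayed > immediate & immediate > 0)))
      stop("each item needs delayed > immediate > 0")
    if (any(delay_days <= 0)) stop("delays must be positive")
    if (any(immediate < 11 | immediate > 80))
      stop("immediate amounts must lie in [11, 80]")
    if (any(delayed < 25 | delayed > 85))
      stop("delayed amounts must lie in [25, 85]")
    if (any(delay_days < 7 | delay_days > 186))
      stop("delays must lie in [7, 186] days")
  })
  tab <- table(instrument$bin)
  if (!setequal(names(tab), c("small", "medium", "large")) || any(tab != 9L))
    stop("instrument must have exactly 9 items per magnitude bin")
  invisible(instrument)
}

#' Read or write an instrument CSV
#'
#' The file format is a plain CSV with header
#' `index,immediate,delayed,delay_days,bin`. Lines starting with `#` are
#' treated as comments.
#'
#' @param path file path.
#' @return `read_instrument()` returns the validated instrument data.frame.
#' @export
read_instrument <- function(path) {
  inst <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  validate_instrument(inst)
  inst
}

#' @rdname read_instrument
#' @param instrument instrument data.frame.
#' @param ... passed on to [write_output_csv()] (e.g. `seed`, `config`).
#' @export
write_instrument <- function(instrument, path, ...) {
  validate_instrument(instrument)
  write_output_csv(instrument, path, ...)
}
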