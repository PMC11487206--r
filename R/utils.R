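#' @importFrom rlang abort warn %||%
#' @importFrom stats rnorm rbinom rpois runif quantile sd weighted.mean median
#' @import dplyr
#' @importFrom tibble tibble as_tibble is_tibble
NULL

# round-half-up at `digits` decimals (report display convention; base round()
# is round-half-even and would print 0.5 specificity cells inconsistently)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

abort_config <- function(msg) abort(msg, class = "fs_config_error")
abort_input <- function(msg) abort(msg, class = "fs_input_error")
abort_scoring <- function(msg) abort(msg, class = "fs_scoring_error")
abort_protocol <- function(msg) abort(msg, class = "fs_protocol_error")
abort_validation <- function(msg) abort(msg, class = "fs_validation_error")

require_columns <- function(data, cols, what = "input") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort_scoring(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(data)
}

# safe ratio: NA (explicitly undefined) when the denominator is zero,
# never silently 0 or 1
ratio_or_na <- function(num, den) {
  ifelse(den > 0, num / den, NA_real_)
}
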