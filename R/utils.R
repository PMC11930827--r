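#' Round half away from zero
#'
#' Commercial rounding used for all printed percentages: ties go away from
#' zero (base `round()` rounds half to even, which prints 47.27 where the
#' published tables print 47.28).
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded to `digits` places.
#' @export
#' @examples
#' round_half_up(0.125, 2)   # 0.13
#' round(0.125, 2)           # 0.12 (banker's rounding)
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

## deterministic seed derivation: one user seed fans out to per-task streams
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 1000L * as.integer(offset)) %% 2147483647L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_records <- function(records) {
  needed <- c("patient_id", "sex", "age", "code")
  if (!is.data.frame(records) || !all(needed %in% names(records))) {
    stop("expected a visit-record data frame with columns ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  invisible(records)
}
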