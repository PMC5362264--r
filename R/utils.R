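# small shared helpers

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; printed percentages in the
#' literature conventionally round half up. Used wherever a percentage is
#' reported alongside its raw value.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return numeric vector rounded half away from zero
#' @examples
#' round_half_up(c(0.5, 1.5, 2.45), 0)
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# stop unless `cond`; message built with sprintf
check_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) abort(sprintf(fmt, ...))
  invisible(TRUE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 1 && x == floor(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)

# run `expr` under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  check_that(is_count(seed + 1), "`seed` must be a single integer, got %s",
             paste(deparse(seed), collapse = ""))
  withr::with_seed(as.integer(seed), expr)
}

# standard error of the mean (sample SD, n - 1 denominator); NA for n < 2
sem <- function(x) {
  n <- sum(!is.na(x))
  if (n < 2) return(NA_real_)
  stats::sd(x, na.rm = TRUE) / sqrt(n)
}
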