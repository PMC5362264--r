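# Condition statistics and diagnostics: means +/- SEM, pairwise t-tests
# with star coding, and the expression-independence check (per-cell ratio
# regressed on expression level).

#' Significance star codes
#'
#' Pure function of the p value with the conventional half-open
#' thresholds: `***` for p < 0.001, `**` for 0.001 <= p < 0.01, `*` for
#' 0.01 <= p < 0.05, `ns` otherwise.
#'
#' @param p numeric vector of p values in `[0, 1]`
#' @return character vector of codes
#' @examples
#' star_code(c(0.2, 0.04, 0.01, 0.001, 1e-5))
#' @export
star_code <- function(p) {
  check_that(is.numeric(p) && all(is.na(p) | (p >= 0 & p <= 1)),
             "`p` must contain p values in [0, 1]")
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns")
}

#' Summarize measurements per condition with significance tests
#'
#' Computes mean and SEM (sample SD, n - 1 denominator) per condition
#' and, when a reference condition is given, a two-sided t-test of every
#' other condition against the reference with star coding. The default
#' Welch (unequal-variance) test can be switched to Student's pooled
#' test. No multiple-testing correction is applied by default, matching
#' the per-comparison star convention; `adjust = "holm"` is available.
#'
#' @param data data frame of replicate-level values
#' @param value column holding the measurement (tidy-eval)
#' @param condition column holding the condition label (tidy-eval)
#' @param reference optional reference condition label for pairwise tests
#' @param var_equal use Student's pooled-variance test instead of Welch
#' @param adjust p-value adjustment: `"none"` (default) or any
#'   [stats::p.adjust()] method
#' @return tibble per condition: `n`, `mean`, `sem`, and (with a
#'   reference) `t`, `df`, `p`, `stars`
#' @export
summarize_conditions <- function(data, value, condition,
                                 reference = NULL, var_equal = FALSE,
                                 adjust = "none") {
  check_that(is.data.frame(data) && nrow(data) >= 1,
             "`data` must be a non-empty data frame")
  value <- rlang::enquo(value)
  condition <- rlang::enquo(condition)
  d <- tibble(condition = as.character(dplyr::pull(data, !!condition)),
              value = dplyr::pull(data, !!value))
  out <- d |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     sem = sem(.data$value), .groups = "drop")
  if (any(out$n < 2)) {
    warn(sprintf("condition(s) with n = 1 have undefined SEM: %s",
                 paste(out$condition[out$n < 2], collapse = ", ")))
  }
  if (is.null(reference)) return(out)
  check_that(reference %in% d$condition,
             "reference condition '%s' not present", reference)
  ref_vals <- d$value[d$condition == reference]
  tests <- purrr::map(out$condition, function(cond) {
    if (cond == reference) {
      return(tibble(t = NA_real_, df = NA_real_, p = NA_real_))
    }
    vals <- d$value[d$condition == cond]
    if (length(vals) < 2 || length(ref_vals) < 2) {
      return(tibble(t = NA_real_, df = NA_real_, p = NA_real_))
    }
    tt <- t.test(vals, ref_vals, var.equal = var_equal,
                 alternative = "two.sided")
    tibble(t = unname(tt$statistic), df = unname(tt$parameter),
           p = tt$p.value)
  }) |> dplyr::bind_rows()
  tests$p <- stats::p.adjust(tests$p, method = adjust)
  dplyr::bind_cols(out, tests) |>
    dplyr::mutate(stars = star_code(.data$p))
}

#' Expression-independence diagnostic
#'
#' Tests whether the periphery/cytosol ratio depends on expression level:
#' ordinary least-squares regression of the per-cell ratio on the
#' per-cell peak intensity, plus the Pearson correlation. A flat slope
#' (p > 0.05) indicates the targeting statistic is independent of how
#' much protein the cell expresses.
#'
#' @param data data frame with one row per cell
#' @param ratio column holding the per-cell ratio (tidy-eval)
#' @param intensity column holding the per-cell peak intensity (tidy-eval)
#' @return one-row tibble: `n`, `slope`, `slope_se`, `p_slope`,
#'   `r` (Pearson), `p_r`
#' @export
expression_independence <- function(data, ratio, intensity) {
  ratio <- rlang::enquo(ratio)
  intensity <- rlang::enquo(intensity)
  d <- tibble(ratio = dplyr::pull(data, !!ratio),
              intensity = dplyr::pull(data, !!intensity))
  check_that(nrow(d) >= 3, "need >= 3 cells, got %d", nrow(d))
  check_that(stats::sd(d$intensity) > 0,
             "zero variance in intensity; regression undefined")
  if (stats::sd(d$ratio) == 0) {
    # constant ratio: flat line fits exactly, no association by definition
    return(tibble(n = nrow(d), slope = 0, slope_se = 0, p_slope = 1,
                  r = 0, p_r = 1))
  }
  fit <- lm(ratio ~ intensity, data = d)
  s <- summary(fit)$coefficients
  ct <- cor.test(d$intensity, d$ratio)
  tibble(n = nrow(d),
         slope = s["intensity", "Estimate"],
         slope_se = s["intensity", "Std. Error"],
         p_slope = s["intensity", "Pr(>|t|)"],
         r = unname(ct$estimate), p_r = ct$p.value)
}
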