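# Synthetic long-format measurement tables with known ground truth.
#
# Noise model: each replicate carries a shared lognormal loading scale
# (sample-to-sample loading differences affect both compartments alike
# and cancel in the ratio), and the stated CV is the coefficient of
# variation of the replicate *ratio*, applied multiplicatively to the
# numerator compartment. The replicate ratio is therefore an unbiased
# estimator of the true ratio.

#' Simulate a two-compartment ratio table
#'
#' Generates a long-format measurement table (fractionation blots:
#' membrane/cytosol; click-chemistry: Cy5/GFP) with known per-condition
#' true ratios.
#'
#' @param conditions data frame with columns `condition` and `true_ratio`
#'   (>= 0)
#' @param type `"fractionation"` (compartments membrane/cytosol) or
#'   `"palmitoylation"` (Cy5/GFP)
#' @param n_replicates replicates per condition
#' @param cv coefficient of variation of the replicate ratio (>= 0)
#' @param base_intensity mean denominator intensity (arbitrary units)
#' @param loading_sd SD (log scale) of the shared per-replicate loading
#' @param seed integer seed (required)
#' @return tibble: `condition`, `replicate`, `compartment`, `intensity`,
#'   with the generating truth in the `"truth"` attribute
#' @export
simulate_ratio_table <- function(conditions,
                                 type = c("fractionation", "palmitoylation"),
                                 n_replicates = 3, cv = 0.1,
                                 base_intensity = 1000, loading_sd = 0.2,
                                 seed) {
  type <- match.arg(type)
  check_that(is.data.frame(conditions) &&
               all(c("condition", "true_ratio") %in% names(conditions)),
             "`conditions` must have columns `condition` and `true_ratio`")
  check_that(all(conditions$true_ratio >= 0), "`true_ratio` must be >= 0")
  check_that(is_number(cv) && cv >= 0, "`cv` must be >= 0")
  check_that(is_count(n_replicates), "`n_replicates` must be a count")
  comp <- switch(type,
                 fractionation = c(num = "membrane", den = "cytosol"),
                 palmitoylation = c(num = "Cy5", den = "GFP"))
  out <- with_seed(seed, {
    purrr::pmap(conditions[c("condition", "true_ratio")],
                function(condition, true_ratio) {
      loading <- exp(rnorm(n_replicates, sd = loading_sd))
      den <- base_intensity * loading
      ratio <- true_ratio * pmax(1 + rnorm(n_replicates, sd = cv), 0)
      tibble(
        condition = condition,
        replicate = rep(seq_len(n_replicates), 2),
        compartment = rep(c(comp[["num"]], comp[["den"]]),
                          each = n_replicates),
        intensity = c(den * ratio, den))
    }) |> dplyr::bind_rows()
  })
  attr(out, "truth") <- tibble(condition = conditions$condition,
                               true_ratio = conditions$true_ratio)
  out
}

#' Simulate a liposome-binding table with GST controls
#'
#' For each (condition, mix), bait beads measure nonspecific + specific
#' binding and matched GST-only beads measure the nonspecific component
#' alone, so control subtraction recovers `true_specific` (exactly at
#' zero CV).
#'
#' @param design data frame with columns `condition`, `mix`,
#'   `true_specific`, `nonspecific`
#' @param n_replicates replicates per condition and mix
#' @param cv multiplicative CV applied independently to every
#'   measurement (>= 0)
#' @param seed integer seed (required)
#' @return tibble: `condition`, `mix`, `replicate`, `compartment`
#'   (bait/GST_control), `intensity`; truth in the `"truth"` attribute.
#'   GST-control rows carry condition `"GST"`.
#' @export
simulate_liposome_table <- function(design, n_replicates = 3, cv = 0.1,
                                    seed) {
  check_that(is.data.frame(design) &&
               all(c("condition", "mix", "true_specific", "nonspecific")
                   %in% names(design)),
             "`design` needs columns condition, mix, true_specific, nonspecific")
  check_that(is_number(cv) && cv >= 0, "`cv` must be >= 0")
  out <- with_seed(seed, {
    bait <- purrr::pmap(design, function(condition, mix, true_specific,
                                         nonspecific) {
      mu <- nonspecific + true_specific
      tibble(condition = condition, mix = mix,
             replicate = seq_len(n_replicates),
             compartment = "bait",
             intensity = pmax(mu * (1 + rnorm(n_replicates, sd = cv)), 0))
    }) |> dplyr::bind_rows()
    ctrl <- design |>
      dplyr::distinct(.data$mix, .data$nonspecific) |>
      purrr::pmap(function(mix, nonspecific) {
        tibble(condition = "GST", mix = mix,
               replicate = seq_len(n_replicates),
               compartment = "GST_control",
               intensity = pmax(nonspecific *
                                  (1 + rnorm(n_replicates, sd = cv)), 0))
      }) |> dplyr::bind_rows()
    dplyr::bind_rows(bait, ctrl)
  })
  attr(out, "truth") <- as_tibble(design)
  out
}

#' Write / read a measurement table as tab-delimited text
#'
#' @param table a measurement table
#' @param path file path
#' @return the path (write) or a tibble (read)
#' @export
write_measurement_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_measurement_table
#' @export
read_measurement_table <- function(path) {
  check_that(file.exists(path), "table not found: %s", path)
  as_tibble(utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE))
}
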