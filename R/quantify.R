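# Ratio quantifiers for biochemical and imaging measurements: membrane/
# cytosol band ratios from fractionation blots, membrane-sheet intensity
# normalized to wild type, palmitate/GFP click-label ratios, and
# GST-control-subtracted liposome binding.
#
# All four consume/produce long-format measurement tables:
# condition | replicate | compartment | intensity (+ optional `mix` for
# liposome assays).

check_measurement_table <- function(table, compartments = NULL) {
  check_that(is.data.frame(table) && nrow(table) >= 1,
             "measurement table must be a non-empty data frame")
  needed <- c("condition", "replicate", "compartment", "intensity")
  missing <- setdiff(needed, names(table))
  check_that(length(missing) == 0, "measurement table lacks column(s): %s",
             paste(missing, collapse = ", "))
  check_that(all(table$intensity >= 0, na.rm = TRUE),
             "intensities must be >= 0")
  if (!is.null(compartments)) {
    extra <- setdiff(unique(table$compartment), compartments)
    check_that(length(extra) == 0,
               "unexpected compartment(s): %s (expected %s)",
               paste(extra, collapse = ", "),
               paste(compartments, collapse = ", "))
  }
  keys <- c("condition", "replicate", "compartment",
            intersect("mix", names(table)))
  dup <- duplicated(table[keys])
  check_that(!any(dup), "duplicate (condition, replicate, compartment) rows")
  invisible(table)
}

# generic per-replicate numerator/denominator ratio used by the
# fractionation and palmitoylation quantifiers
replicate_ratio <- function(table, num, den, ratio_name) {
  check_measurement_table(table, compartments = c(num, den))
  wide <- table |>
    dplyr::select("condition", "replicate", "compartment", "intensity") |>
    tidyr::pivot_wider(names_from = "compartment", values_from = "intensity")
  check_that(all(c(num, den) %in% names(wide)) &&
               !anyNA(wide[[num]]) && !anyNA(wide[[den]]),
             "each replicate needs both '%s' and '%s' measurements", num, den)
  bad <- wide[[den]] == 0
  excluded <- wide[bad, c("condition", "replicate")]
  if (any(bad)) {
    warn(sprintf(
      "excluded %d replicate(s) with zero %s intensity: %s",
      sum(bad), den,
      paste(sprintf("%s/%d", excluded$condition, excluded$replicate),
            collapse = ", ")))
  }
  out <- wide[!bad, ] |>
    dplyr::mutate("{ratio_name}" := .data[[num]] / .data[[den]]) |>
    dplyr::select("condition", "replicate", dplyr::all_of(c(num, den)),
                  dplyr::all_of(ratio_name))
  attr(out, "excluded") <- excluded
  out
}

#' Membrane/cytosol band ratio per replicate
#'
#' For each (condition, replicate) with `membrane` and `cytosol`
#' compartments, computes the band-intensity ratio membrane / cytosol.
#' Replicates with zero cytosol intensity are excluded with a warning
#' (recorded in the `"excluded"` attribute). Summarize across replicates
#' with [summarize_conditions()].
#'
#' @param table long-format measurement table with compartments
#'   `membrane` and `cytosol`
#' @return tibble with one row per retained replicate:
#'   `condition`, `replicate`, `membrane`, `cytosol`, `ratio`
#' @export
membrane_cytosol_ratio <- function(table) {
  replicate_ratio(table, "membrane", "cytosol", "ratio")
}

#' Palmitate/GFP click-label ratio per replicate
#'
#' Cy5 (clicked palmitate) intensity divided by GFP (expression)
#' intensity per replicate; GFP = 0 replicates are excluded with a
#' warning.
#'
#' @param table long-format measurement table with compartments `Cy5` and
#'   `GFP`
#' @return tibble with one row per retained replicate:
#'   `condition`, `replicate`, `Cy5`, `GFP`, `ratio`
#' @export
palmitoylation_ratio <- function(table) {
  replicate_ratio(table, "Cy5", "GFP", "ratio")
}

#' Quantify membrane sheets in a two-channel image
#'
#' Measures the background-subtracted mean green intensity in square ROIs
#' centred on candidate sheets, gated on the membrane-marker (blue)
#' channel: an ROI is accepted only if its mean blue intensity exceeds
#' `blue_threshold` (the marker confirms an intact sheet).
#'
#' @param green,blue [micro_image()]s (or matrices) of the protein and
#'   marker channels
#' @param roi_centers data frame with columns `row`, `col` (ROI centres,
#'   px); one row per candidate sheet
#' @param roi_edge ROI edge length (px), default 30
#' @param background green-channel background to subtract
#' @param blue_threshold minimum mean blue intensity for a valid sheet
#' @return tibble with one row per ROI: `row`, `col`, `blue_mean`,
#'   `sheet_ok`, `intensity` (bg-subtracted green mean; NA when gated out)
#' @export
measure_sheet_rois <- function(green, blue, roi_centers, roi_edge = 30,
                               background = 0, blue_threshold = 100) {
  g <- if (inherits(green, "micro_image")) green$data else green
  b <- if (inherits(blue, "micro_image")) blue$data else blue
  check_that(all(dim(g) == dim(b)), "green and blue channels differ in size")
  check_that(is.data.frame(roi_centers) &&
               all(c("row", "col") %in% names(roi_centers)),
             "`roi_centers` must have columns `row` and `col`")
  half <- floor(roi_edge / 2)
  rows <- lapply(seq_len(nrow(roi_centers)), function(i) {
    row <- roi_centers$row[i]; col <- roi_centers$col[i]
    r0 <- row - half; r1 <- r0 + roi_edge - 1
    c0 <- col - half; c1 <- c0 + roi_edge - 1
    if (r0 < 1 || c0 < 1 || r1 > nrow(g) || c1 > ncol(g)) {
      abort(sprintf(
        "%d x %d ROI at (%g, %g) extends outside the %d x %d image",
        roi_edge, roi_edge, row, col, nrow(g), ncol(g)))
    }
    blue_mean <- mean(b[r0:r1, c0:c1])
    ok <- blue_mean > blue_threshold
    tibble(row = row, col = col, blue_mean = blue_mean, sheet_ok = ok,
           intensity = if (ok) mean(g[r0:r1, c0:c1]) - background else NA_real_)
  })
  dplyr::bind_rows(rows)
}

#' Condition means of sheet intensities, normalized to wild type
#'
#' Averages per-sheet background-subtracted intensities within each
#' condition, then divides every condition mean by the reference
#' (wild-type) condition mean, so the reference maps to exactly 1.
#'
#' @param sheets data frame with columns `condition` and `intensity` (one
#'   row per sheet, e.g. stacked [measure_sheet_rois()] output)
#' @param reference label of the wild-type condition
#' @return tibble per condition: `n_sheets`, `mean_intensity`,
#'   `normalized` (reference = 1), `sem_normalized`
#' @export
sheet_quantification <- function(sheets, reference = "wt") {
  check_that(is.data.frame(sheets) &&
               all(c("condition", "intensity") %in% names(sheets)),
             "`sheets` must have columns `condition` and `intensity`")
  sheets <- sheets[!is.na(sheets$intensity), ]
  check_that(nrow(sheets) > 0, "no valid sheets to quantify")
  if (!reference %in% sheets$condition) {
    abort(sprintf(
      "reference condition '%s' not present; normalization refused", reference))
  }
  per_cond <- sheets |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(n_sheets = dplyr::n(),
                     mean_intensity = mean(.data$intensity),
                     sem_intensity = sem(.data$intensity),
                     .groups = "drop")
  ref_mean <- per_cond$mean_intensity[per_cond$condition == reference]
  check_that(ref_mean != 0, "reference condition mean is zero; cannot normalize")
  dplyr::mutate(per_cond,
                normalized = .data$mean_intensity / ref_mean,
                sem_normalized = .data$sem_intensity / ref_mean)
}

#' GST-control-subtracted liposome binding
#'
#' For each (condition, lipid mix), subtracts nonspecific binding
#' measured on GST-only beads from the bait signal. Two pairing modes:
#' `"replicate"` (default) subtracts the control of the same replicate
#' index within the mix, propagating replicate-level variance;
#' `"condition_mean"` subtracts the mean of the controls of the mix from
#' every bait replicate. Negative specific binding is retained (clipping
#' would bias condition means) and flagged in the `negative` column.
#'
#' @param table long-format table with compartments `bait` and
#'   `GST_control`; an optional `mix` column identifies the lipid mixture
#'   (a single implicit mix otherwise)
#' @param pairing `"replicate"` or `"condition_mean"`
#' @return tibble per retained (condition, mix, replicate): `bait`,
#'   `control`, `specific`, `negative`
#' @export
specific_liposome_binding <- function(table,
                                      pairing = c("replicate", "condition_mean")) {
  pairing <- match.arg(pairing)
  if (!"mix" %in% names(table)) table$mix <- "mix1"
  check_measurement_table(table, compartments = c("bait", "GST_control"))
  bait <- table[table$compartment == "bait", ]
  ctrl <- table[table$compartment == "GST_control", ]
  mixes <- unique(bait$mix)
  missing <- setdiff(mixes, unique(ctrl$mix))
  if (length(missing) > 0) {
    abort(sprintf("no GST control for lipid mix '%s'", missing[1]))
  }
  if (pairing == "replicate") {
    paired <- dplyr::inner_join(
      dplyr::select(bait, "condition", "mix", "replicate", bait = "intensity"),
      dplyr::select(ctrl, "mix", "replicate", control = "intensity"),
      by = c("mix", "replicate"))
    if (nrow(paired) < nrow(bait)) {
      un <- dplyr::anti_join(bait, ctrl, by = c("mix", "replicate"))
      abort(sprintf("no matched GST control for mix '%s', replicate %d",
                    un$mix[1], un$replicate[1]))
    }
  } else {
    ctrl_mean <- ctrl |>
      dplyr::group_by(.data$mix) |>
      dplyr::summarise(control = mean(.data$intensity), .groups = "drop")
    paired <- dplyr::inner_join(
      dplyr::select(bait, "condition", "mix", "replicate", bait = "intensity"),
      ctrl_mean, by = "mix")
  }
  dplyr::mutate(paired,
                specific = .data$bait - .data$control,
                negative = .data$specific < 0)
}
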