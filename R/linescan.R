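# Periphery/cytosol quantification from confocal linescans.
#
# A linescan is 100 samples at 1 px spacing along a direction pointing
# from outside the cell toward the interior, each sample averaged over a
# 5 px width perpendicular to the scan. After background correction and
# normalization to the membrane peak, the cytosolic level is the mean of
# the five samples starting 10 px interior to the peak (indices
# peak+10 .. peak+14), and the periphery/cytosol ratio is
# 1 / cytosol_mean.

LINESCAN_LENGTH <- 100L

#' Extract a width-averaged linescan from an image
#'
#' Samples 100 points at 1 px spacing along `direction` starting at
#' `anchor`, each averaged over `width` samples spaced 1 px along the
#' perpendicular. Values at sub-pixel coordinates are bilinearly
#' interpolated; axis-aligned scans on the pixel grid reduce to exact
#' row/column slicing.
#'
#' @param image a [micro_image()] or numeric matrix
#' @param anchor `c(row, col)` of the first sample (1-based, px)
#' @param direction `c(row, col)` direction, outside -> inside; need not
#'   be normalized
#' @param width odd averaging width (px), default 5
#' @return a `linescan` tibble with columns `index` (1..100) and `value`,
#'   carrying anchor/direction/width attributes
#' @export
extract_linescan <- function(image, anchor, direction, width = 5) {
  img <- if (inherits(image, "micro_image")) image$data else image
  check_that(is.matrix(img) && is.numeric(img), "`image` must be a numeric matrix or micro_image")
  check_that(is.numeric(anchor) && length(anchor) == 2,
             "`anchor` must be c(row, col)")
  check_that(is.numeric(direction) && length(direction) == 2 &&
               any(direction != 0), "`direction` must be a nonzero c(row, col) vector")
  check_that(is_count(width) && width %% 2 == 1, "`width` must be an odd count")
  dir <- direction / sqrt(sum(direction^2))
  perp <- c(-dir[2], dir[1])
  offs <- seq(-(width - 1) / 2, (width - 1) / 2)
  k <- seq_len(LINESCAN_LENGTH) - 1
  pos_r <- outer(k, offs, function(a, b) anchor[1] + a * dir[1] + b * perp[1])
  pos_c <- outer(k, offs, function(a, b) anchor[2] + a * dir[2] + b * perp[2])
  over_r <- max(0, max(pos_r) - nrow(img), 1 - min(pos_r))
  over_c <- max(0, max(pos_c) - ncol(img), 1 - min(pos_c))
  if (over_r > 0 || over_c > 0) {
    abort(sprintf(
      "linescan footprint exits the image by %.1f px (rows) / %.1f px (cols)",
      over_r, over_c))
  }
  vals <- bilinear_sample(img, as.vector(pos_r), as.vector(pos_c))
  trace <- tibble(index = seq_len(LINESCAN_LENGTH),
                  value = rowMeans(matrix(vals, nrow = LINESCAN_LENGTH)))
  class(trace) <- c("linescan", class(trace))
  attr(trace, "anchor") <- anchor
  attr(trace, "direction") <- dir
  attr(trace, "width") <- width
  attr(trace, "normalized") <- FALSE
  trace
}

linescan_from_values <- function(values) {
  check_that(length(values) == LINESCAN_LENGTH,
             "a linescan has exactly %d samples, got %d",
             LINESCAN_LENGTH, length(values))
  trace <- tibble(index = seq_len(LINESCAN_LENGTH), value = as.numeric(values))
  class(trace) <- c("linescan", class(trace))
  attr(trace, "normalized") <- FALSE
  trace
}

is_normalized <- function(trace) isTRUE(attr(trace, "normalized"))

#' Background-correct and peak-normalize a linescan
#'
#' Subtracts the background and divides by the maximum of the corrected
#' trace within the membrane search window (default: the whole trace),
#' recording the peak index. Ties are broken by first occurrence. A
#' non-positive peak after background subtraction is rejected as an
#' uninterpretable cell.
#'
#' @param trace a `linescan` from [extract_linescan()]
#' @param background background level to subtract (>= 0). The default
#'   `NULL` estimates it as the mean of the first 10 samples, which for
#'   the standard geometry lie outside the cell.
#' @param search_window optional `c(first, last)` index window in which
#'   the membrane peak is sought
#' @return the normalized `linescan`, with attribute `peak_index`
#' @export
normalize_trace <- function(trace, background = NULL, search_window = NULL) {
  check_that(is.data.frame(trace) && "value" %in% names(trace),
             "`trace` must be a linescan")
  check_that(!is_normalized(trace), "trace is already normalized")
  v <- trace$value
  if (is.null(background)) background <- mean(v[1:10])
  check_that(is_number(background) && background >= 0,
             "`background` must be >= 0")
  v <- v - background
  if (is.null(search_window)) search_window <- c(1L, length(v))
  sw <- check_window(search_window, length(v))
  peak_index <- sw[1] - 1L + which.max(v[sw[1]:sw[2]])
  peak <- v[peak_index]
  if (peak <= 0) {
    abort("peak intensity is not positive after background subtraction; cell uninterpretable")
  }
  out <- trace
  out$value <- v / peak
  attr(out, "normalized") <- TRUE
  attr(out, "background") <- background
  attr(out, "peak_index") <- as.integer(peak_index)
  out
}

#' Align traces on their membrane peaks and average
#'
#' Shifts each normalized trace so that all membrane peaks coincide at the
#' median peak index, then averages per index over the traces that cover
#' it. Indices supported by fewer than `min_support` (default 80%) of the
#' traces are dropped.
#'
#' @param traces list of normalized `linescan`s
#' @param min_support minimum fraction of traces contributing to a
#'   retained index
#' @return tibble with columns `index`, `mean`, `sd`, `n_traces`, of class
#'   `linescan` (aliasing `value = mean`), with attribute `peak_index`
#'   (the common aligned peak)
#' @export
align_and_average <- function(traces, min_support = 0.8) {
  check_that(is.list(traces) && length(traces) >= 1,
             "`traces` must be a non-empty list of normalized linescans")
  check_that(all(vapply(traces, is_normalized, TRUE)),
             "all traces must be normalized (see normalize_trace())")
  peaks <- vapply(traces, function(tr) attr(tr, "peak_index"), 1L)
  target <- as.integer(round(median(peaks)))
  n <- length(traces)
  acc <- matrix(NA_real_, nrow = LINESCAN_LENGTH, ncol = n)
  for (i in seq_len(n)) {
    shift <- target - peaks[i]
    src <- seq_len(LINESCAN_LENGTH) - shift
    ok <- src >= 1 & src <= LINESCAN_LENGTH
    acc[which(ok), i] <- traces[[i]]$value[src[ok]]
  }
  support <- rowSums(!is.na(acc))
  keep <- which(support >= min_support * n)
  out <- tibble(
    index = keep,
    value = apply(acc[keep, , drop = FALSE], 1, mean, na.rm = TRUE),
    sd = apply(acc[keep, , drop = FALSE], 1, stats::sd, na.rm = TRUE),
    n_traces = support[keep])
  class(out) <- c("linescan", class(out))
  attr(out, "normalized") <- TRUE
  attr(out, "peak_index") <- target
  attr(out, "n_traces") <- n
  out
}

#' Periphery/cytosol ratio of a normalized trace
#'
#' The cytosolic level is the mean over the five samples starting 10 px
#' interior to the membrane peak (indices `peak+10 .. peak+14`; the
#' interior side is the direction of increasing index for a trace
#' recorded outside -> inside). With the peak normalized to 1, the ratio
#' is `1 / cytosol_mean`.
#'
#' @param trace a normalized `linescan` (single or averaged)
#' @return one-row tibble: `ratio`, `peak_value`, `cytosol_mean`,
#'   `window_start`, `window_end`, `n_traces`
#' @export
periphery_cytosol_ratio <- function(trace) {
  check_that(is.data.frame(trace) && is_normalized(trace),
             "`trace` must be a normalized linescan")
  peak <- attr(trace, "peak_index")
  check_that(!is.null(peak), "trace carries no peak index")
  win <- peak + 10:14
  idx <- trace$index
  if (!all(win %in% idx)) {
    abort(sprintf(
      "cytosol window %d..%d lies outside the trace (indices %d..%d)",
      win[1], win[5], min(idx), max(idx)))
  }
  vals <- trace$value[match(win, idx)]
  cyt <- mean(vals)
  if (cyt <= 0) {
    abort("cytosol mean is not positive; ratio undefined")
  }
  peak_value <- trace$value[match(peak, idx)]
  tibble(ratio = peak_value / cyt,
         peak_value = peak_value,
         cytosol_mean = cyt,
         window_start = win[1], window_end = win[5],
         n_traces = attr(trace, "n_traces") %||% 1L)
}

#' Estimate the periphery/cytosol ratio of a simulated cell
#'
#' Convenience wrapper chaining [extract_linescan()] (at the geometry
#' recorded in the ground truth), [normalize_trace()] (background from the
#' known level or the extracellular samples) and
#' [periphery_cytosol_ratio()].
#'
#' @param sim a `simulated_cell` from [simulate_equatorial_cell()]
#' @param background background to subtract; defaults to the true
#'   simulated background level
#' @param search_halfwidth half-width (px) of the membrane-peak search
#'   window around the known membrane position. Mirrors the manual
#'   procedure, where the scan is anchored on the visible membrane: for a
#'   cell without a membrane pool the trace is flat and an unconstrained
#'   maximum would wander arbitrarily far into the cytosol.
#' @return one-row tibble as [periphery_cytosol_ratio()], plus
#'   `peak_intensity` (raw background-corrected peak, for
#'   expression-level diagnostics) and `analytic_ratio` (truth)
#' @export
cell_ratio <- function(sim, background = sim$truth$background_level,
                       search_halfwidth = 10) {
  check_that(inherits(sim, "simulated_cell"), "`sim` must be a simulated_cell")
  tr <- extract_linescan(sim$image,
                         anchor = c(sim$truth$anchor_row, sim$truth$anchor_col),
                         direction = c(sim$truth$direction_row,
                                       sim$truth$direction_col))
  mi <- sim$truth$membrane_index
  sw <- c(max(1L, mi - search_halfwidth),
          min(LINESCAN_LENGTH, mi + search_halfwidth))
  raw_peak <- max(tr$value[sw[1]:sw[2]]) - background
  ntr <- normalize_trace(tr, background = background, search_window = sw)
  dplyr::mutate(periphery_cytosol_ratio(ntr),
                peak_index = attr(ntr, "peak_index"),
                peak_intensity = raw_peak,
                analytic_ratio = sim$truth$analytic_ratio)
}

#' Read a linescan annotation table
#'
#' Annotations record where the operator placed each scan: one row per
#' cell with the image it belongs to, the anchor pixel and the
#' outside-to-inside direction. Tab-delimited with a header line
#' `image  anchor_row  anchor_col  dir_row  dir_col`.
#'
#' @param path path to the tab-delimited annotation file
#' @return tibble with columns `image`, `anchor_row`, `anchor_col`,
#'   `dir_row`, `dir_col`
#' @export
read_linescan_annotations <- function(path) {
  check_that(file.exists(path), "annotation file not found: %s", path)
  ann <- as_tibble(utils::read.delim(path, sep = "\t",
                                     stringsAsFactors = FALSE))
  needed <- c("image", "anchor_row", "anchor_col", "dir_row", "dir_col")
  missing <- setdiff(needed, names(ann))
  check_that(length(missing) == 0,
             "annotation file lacks column(s): %s",
             paste(missing, collapse = ", "))
  ann
}

#' Two-level condition summary of per-cell ratios
#'
#' Aggregates per-cell ratios the way imaging experiments are summarized:
#' cells are first averaged within each imaging day, then the condition
#' mean and SEM are computed across day means (SEM = SD / sqrt(n_days),
#' undefined for a single day).
#'
#' @param ratios data frame with one row per cell
#' @param value column holding the per-cell ratio (tidy-eval)
#' @param day column identifying the imaging day (tidy-eval)
#' @param condition optional column identifying the condition; omit for a
#'   single-condition summary
#' @return tibble with one row per condition: `n_days`, `n_cells`,
#'   `mean`, `sem`
#' @export
condition_summary <- function(ratios, value, day, condition = NULL) {
  check_that(is.data.frame(ratios) && nrow(ratios) >= 1,
             "`ratios` must be a non-empty data frame")
  value <- rlang::enquo(value)
  day <- rlang::enquo(day)
  condition <- rlang::enquo(condition)
  grouped <- if (rlang::quo_is_null(condition)) {
    dplyr::mutate(ratios, .condition = "all")
  } else {
    dplyr::mutate(ratios, .condition = !!condition)
  }
  day_means <- grouped |>
    dplyr::group_by(.data$.condition, .day = !!day) |>
    dplyr::summarise(day_mean = mean(!!value), n_cells = dplyr::n(),
                     .groups = "drop")
  day_means |>
    dplyr::group_by(condition = .data$.condition) |>
    dplyr::summarise(n_days = dplyr::n(),
                     n_cells = sum(.data$n_cells),
                     mean = mean(.data$day_mean),
                     sem = sem(.data$day_mean),
                     .groups = "drop")
}
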