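# Residue-charge model of the cysteine-rich region (CRR)
#
# Charge bookkeeping convention: basic = {K, R}, acidic = {D, E};
# histidine is never counted (the constructs of interest alter lysines and
# arginines only, and the nominal construct charges in this system are
# computed without histidine). Residue numbering is 1-based, matching
# construct names such as R191A or C85.

AA_CANONICAL <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
AA_BASIC  <- c("K", "R")
AA_ACIDIC <- c("D", "E")

# split a sequence into residues after validating it; names unused
check_sequence <- function(sequence, allow_empty = FALSE) {
  check_that(is.character(sequence) && length(sequence) == 1 && !is.na(sequence),
             "`sequence` must be a single character string")
  if (!allow_empty) {
    check_that(nzchar(sequence), "`sequence` must be non-empty")
  }
  res <- strsplit(sequence, "")[[1]]
  bad <- which(!(res %in% AA_CANONICAL))
  if (length(bad) > 0) {
    abort(sprintf(
      "non-canonical residue '%s' at position %d (only the 20 standard 1-letter codes are allowed)",
      res[bad[1]], bad[1]))
  }
  res
}

check_window <- function(window, n) {
  check_that(is.numeric(window) && length(window) == 2 && all(is.finite(window)),
             "`window` must be two positions c(start, end)")
  check_that(window[1] == floor(window[1]) && window[2] == floor(window[2]),
             "`window` positions must be integers")
  check_that(window[1] >= 1 && window[2] <= n,
             "window [%d, %d] outside sequence bounds [1, %d]",
             window[1], window[2], n)
  as.integer(window)
}

#' Net charge of a sequence window
#'
#' Counts basic residues (K, R) minus acidic residues (D, E) over a residue
#' window. Histidine is not counted. This is the nominal charge used to
#' label CRR constructs (e.g. wild-type SNAP25 CRR = +3).
#'
#' @param sequence amino-acid string (1-letter codes, uppercase)
#' @param window `c(start, end)`, 1-based inclusive residue positions;
#'   defaults to the whole sequence. `start > end` denotes an empty window
#'   (net charge 0).
#' @return integer net charge in elementary charges
#' @examples
#' net_charge("KKCCKK")            # +4
#' net_charge("DEKR")              # 0
#' net_charge("KDCCEK", c(2, 5))   # -2
#' @seealso [charge_composition()], [crr_charge_table()]
#' @export
net_charge <- function(sequence, window = NULL) {
  res <- check_sequence(sequence, allow_empty = TRUE)
  if (is.null(window)) window <- c(1L, length(res))
  if (window[1] > window[2]) return(0L)  # empty window
  window <- check_window(window, length(res))
  w <- res[window[1]:window[2]]
  as.integer(sum(w %in% AA_BASIC) - sum(w %in% AA_ACIDIC))
}

#' Charged-residue composition of a protein
#'
#' Whole-sequence composition summary: counts of basic (K+R) and acidic
#' (D+E) residues and the percentage of the full length each represents,
#' reported both raw and rounded half-up to the nearest integer (the
#' rounding used when such percentages are printed).
#'
#' @param sequence amino-acid string (1-letter codes, uppercase), non-empty
#' @return a one-row tibble with columns `length`, `n_basic`, `n_acidic`,
#'   `net_charge`, `percent_positive`, `percent_negative` (raw) and
#'   `percent_positive_rounded`, `percent_negative_rounded`
#' @examples
#' charge_composition("DEKR")
#' @export
charge_composition <- function(sequence) {
  res <- check_sequence(sequence)
  n <- length(res)
  n_basic <- sum(res %in% AA_BASIC)
  n_acidic <- sum(res %in% AA_ACIDIC)
  pct_pos <- 100 * n_basic / n
  pct_neg <- 100 * n_acidic / n
  tibble(
    length = n,
    n_basic = as.integer(n_basic),
    n_acidic = as.integer(n_acidic),
    net_charge = as.integer(n_basic - n_acidic),
    percent_positive = pct_pos,
    percent_negative = pct_neg,
    percent_positive_rounded = as.integer(round_half_up(pct_pos)),
    percent_negative_rounded = as.integer(round_half_up(pct_neg))
  )
}
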