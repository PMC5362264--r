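# Protein constructs: a named sequence, an optional CRR window, and an
# ordered list of point substitutions. Mutations are validated against the
# base sequence (from-residue must match) to guard against off-by-one
# errors in hand-entered substitution sets.

#' Define a protein construct
#'
#' @param label construct name, e.g. `"wt-SNAP25 (+3)"`
#' @param sequence base amino-acid sequence (1-letter codes)
#' @param crr_window optional `c(start, end)` window of the cysteine-rich
#'   region, 1-based inclusive
#' @param mutations optional tibble/data.frame with columns `position`
#'   (1-based), `from` and `to` (1-letter codes), applied in row order; or
#'   a character vector of compact codes like `"K79A"`
#' @return an object of class `protein_construct`
#' @examples
#' pc <- protein_construct("toy", "KKCCKK", crr_window = c(1, 6),
#'                         mutations = c("K1A", "K6A"))
#' construct_sequence(pc)
#' @export
protein_construct <- function(label, sequence, crr_window = NULL,
                              mutations = NULL) {
  check_that(is.character(label) && length(label) == 1 && nzchar(label),
             "`label` must be a non-empty string")
  res <- check_sequence(sequence)
  if (!is.null(crr_window)) {
    crr_window <- check_window(crr_window, length(res))
  }
  mutations <- as_mutation_table(mutations)
  x <- structure(
    list(label = label, sequence = sequence, crr_window = crr_window,
         mutations = mutations),
    class = "protein_construct")
  validate_mutations(x)
  x
}

#' @export
print.protein_construct <- function(x, ...) {
  cat(sprintf("<protein_construct> %s\n", x$label))
  cat(sprintf("  sequence: %d aa\n", nchar(x$sequence)))
  if (!is.null(x$crr_window)) {
    cat(sprintf("  CRR window: %d-%d\n", x$crr_window[1], x$crr_window[2]))
  }
  if (nrow(x$mutations) > 0) {
    cat(sprintf("  mutations: %s\n",
                paste0(x$mutations$from, x$mutations$position,
                       x$mutations$to, collapse = ", ")))
  }
  invisible(x)
}

# accept NULL, a data frame, or compact codes ("K79A")
as_mutation_table <- function(mutations) {
  if (is.null(mutations)) {
    return(tibble(position = integer(), from = character(), to = character()))
  }
  if (is.character(mutations)) {
    m <- regmatches(mutations,
                    regexec("^([A-Y])([0-9]+)([A-Y])$", mutations))
    bad <- vapply(m, length, 1L) != 4
    if (any(bad)) {
      abort(sprintf("cannot parse mutation code '%s' (expected e.g. \"K79A\")",
                    mutations[which(bad)[1]]))
    }
    return(tibble(
      position = as.integer(vapply(m, `[`, "", 3)),
      from = vapply(m, `[`, "", 2),
      to = vapply(m, `[`, "", 4)))
  }
  check_that(is.data.frame(mutations) &&
               all(c("position", "from", "to") %in% names(mutations)),
             "`mutations` must have columns position, from, to")
  tibble(position = as.integer(mutations$position),
         from = as.character(mutations$from),
         to = as.character(mutations$to))
}

validate_mutations <- function(construct) {
  res <- strsplit(construct$sequence, "")[[1]]
  m <- construct$mutations
  for (i in seq_len(nrow(m))) {
    check_that(m$position[i] >= 1 && m$position[i] <= length(res),
               "mutation %d: position %d outside sequence (length %d)",
               i, m$position[i], length(res))
    found <- res[m$position[i]]
    if (found != m$from[i]) {
      abort(sprintf(
        "mutation %s%d%s: base sequence has '%s' at position %d, not '%s'",
        m$from[i], m$position[i], m$to[i], found, m$position[i], m$from[i]))
    }
    check_that(m$to[i] %in% AA_CANONICAL,
               "mutation %d: target residue '%s' is not canonical", i, m$to[i])
  }
  invisible(construct)
}

#' Apply a construct's mutations to its base sequence
#'
#' Returns the mutated amino-acid sequence. Length is unchanged; an empty
#' mutation list returns the base sequence (idempotent).
#'
#' @param construct a [protein_construct()]
#' @return mutated sequence as a single string
#' @export
construct_sequence <- function(construct) {
  check_that(inherits(construct, "protein_construct"),
             "`construct` must be a protein_construct")
  validate_mutations(construct)
  res <- strsplit(construct$sequence, "")[[1]]
  m <- construct$mutations
  res[m$position] <- m$to
  paste(res, collapse = "")
}

#' Mutation-set builders for charge-series constructs
#'
#' Convenience builders for the standard substitution patterns used in CRR
#' charge series: lysine-to-alanine or lysine-to-leucine at listed
#' positions (each removes one positive charge), and cysteine-to-glycine
#' at every cysteine of the CRR window (palmitoylation-dead control,
#' charge-neutral).
#'
#' @param sequence base sequence the positions refer to
#' @param positions 1-based lysine positions to substitute
#' @return a mutation tibble suitable for [protein_construct()]
#' @examples
#' mutations_k_to_a("AKCK", c(2, 4))
#' @export
mutations_k_to_a <- function(sequence, positions) {
  mutations_from_to(sequence, positions, "K", "A")
}

#' @rdname mutations_k_to_a
#' @export
mutations_k_to_l <- function(sequence, positions) {
  mutations_from_to(sequence, positions, "K", "L")
}

#' @rdname mutations_k_to_a
#' @param crr_window `c(start, end)` window in which every cysteine is
#'   exchanged for glycine
#' @export
mutations_c_to_g <- function(sequence, crr_window) {
  res <- check_sequence(sequence)
  crr_window <- check_window(crr_window, length(res))
  pos <- which(res == "C")
  pos <- pos[pos >= crr_window[1] & pos <= crr_window[2]]
  check_that(length(pos) > 0, "no cysteines inside window [%d, %d]",
             crr_window[1], crr_window[2])
  mutations_from_to(sequence, pos, "C", "G")
}

mutations_from_to <- function(sequence, positions, from, to) {
  res <- check_sequence(sequence)
  check_that(all(positions >= 1 & positions <= length(res)),
             "positions outside sequence bounds")
  found <- res[positions]
  if (any(found != from)) {
    i <- which(found != from)[1]
    abort(sprintf("position %d has '%s', expected '%s'",
                  positions[i], found[i], from))
  }
  tibble(position = as.integer(positions),
         from = rep(from, length(positions)),
         to = rep(to, length(positions)))
}

#' CRR charge table for a set of constructs
#'
#' Applies each construct's mutations and computes the net charge of its
#' CRR window, one row per construct in the order given. All constructs
#' must carry a CRR window and labels must be unique.
#'
#' @param constructs a list of [protein_construct()] objects
#' @return tibble with columns `label`, `window_start`, `window_end`,
#'   `net_charge`
#' @export
crr_charge_table <- function(constructs) {
  check_that(is.list(constructs) && length(constructs) > 0 &&
               all(vapply(constructs, inherits, TRUE, "protein_construct")),
             "`constructs` must be a non-empty list of protein_construct objects")
  labels <- vapply(constructs, `[[`, "", "label")
  if (anyDuplicated(labels)) {
    abort(sprintf("duplicate construct label '%s'",
                  labels[duplicated(labels)][1]))
  }
  rows <- purrr::map(constructs, function(pc) {
    if (is.null(pc$crr_window)) {
      abort(sprintf("construct '%s' has no CRR window", pc$label))
    }
    tibble(label = pc$label,
           window_start = pc$crr_window[1],
           window_end = pc$crr_window[2],
           net_charge = net_charge(construct_sequence(pc), pc$crr_window))
  })
  dplyr::bind_rows(rows)
}

#' Read protein sequences from a FASTA file
#'
#' Uses Biostrings when available, otherwise a minimal reader for plain
#' (uncompressed) protein FASTA. The first whitespace-delimited token of
#' each description line becomes the label.
#'
#' @param path path to a FASTA file
#' @return tibble with columns `label`, `description`, `sequence`
#' @export
read_protein_fasta <- function(path) {
  check_that(file.exists(path), "FASTA file not found: %s", path)
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::readAAStringSet(path)
    desc <- names(ss)
    seqs <- as.character(ss)
  } else {
    lines <- readLines(path)
    hdr <- grepl("^>", lines)
    check_that(any(hdr), "no FASTA records in %s", path)
    idx <- cumsum(hdr)
    desc <- sub("^>", "", lines[hdr])
    seqs <- vapply(seq_along(desc), function(i) {
      paste(lines[idx == i & !hdr], collapse = "")
    }, "")
  }
  tibble(
    label = unname(vapply(strsplit(desc, "\\s+"), `[`, "", 1)),
    description = unname(desc),
    sequence = unname(toupper(gsub("[ *]", "", seqs)))
  )
}

#' Bundled rat SNAP-25B reference sequence
#'
#' Returns the full-length rat SNAP-25B sequence (RefSeq NP_112253.1,
#' identical to UniProt P60881; 206 residues), shipped with the package as
#' a plain-text FASTA file.
#'
#' @return the 206-residue sequence as a single string
#' @seealso [snap25_crr_window()]
#' @export
snap25b_sequence <- function() {
  path <- system.file("extdata", "SNAP25B_rat_NP_112253.1.fasta",
                      package = "memtarget")
  read_protein_fasta(path)$sequence[[1]]
}

#' Working CRR window for rat SNAP-25B
#'
#' The cysteine-rich region of SNAP25 is described in the literature by its
#' residue content rather than numeric bounds: four palmitoylated cysteines
#' (C85, C88, C90, C92) flanked by four lysines on each side, with four
#' acidic residues upstream and one downstream. The window returned here,
#' residues 70-103, is the minimal window containing exactly those
#' residues (K72, K76, K79, K83 / K94, K96, K102, K103; D70, E73, E75,
#' D80, D99), and carries the wild-type net charge of +3. For SNAP23 the
#' published precedent is residues 64-100.
#'
#' Every charge operation in this package takes an explicit window; this
#' helper documents the package's working definition for SNAP25 rather
#' than hard-wiring it anywhere.
#'
#' @return `c(start = 70, end = 103)`
#' @export
snap25_crr_window <- function() {
  c(start = 70L, end = 103L)
}

#' Flanking-lysine positions of the SNAP25 CRR
#'
#' Positions of the eight lysines flanking the SNAP25 cysteine cluster,
#' split into the inner (proximal) and outer (distal) four used by the
#' charge-reduction constructs: substituting either set with alanine gives
#' a CRR net charge of -1, substituting all eight gives -5.
#'
#' @return named list with integer vectors `proximal`, `distal`, `all`
#' @export
snap25_flanking_lysines <- function() {
  proximal <- c(79L, 83L, 94L, 96L)
  distal <- c(72L, 76L, 102L, 103L)
  list(proximal = proximal, distal = distal, all = sort(c(proximal, distal)))
}
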