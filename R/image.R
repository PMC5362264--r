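# Image container and primitive image operations.
#
# A micro_image is a numeric matrix [row, col] with physical pixel size
# (nm) and a channel label. 1-based indices, pixel centers at integer
# coordinates.

#' Construct a microscopy image
#'
#' @param data numeric matrix of intensities, indexed `[row, col]`
#' @param pixel_size_nm physical pixel edge length in nanometres
#' @param channel channel label, e.g. `"GFP"`
#' @return an object of class `micro_image`
#' @export
micro_image <- function(data, pixel_size_nm = 137, channel = "GFP") {
  check_that(is.matrix(data) && is.numeric(data), "`data` must be a numeric matrix")
  check_that(is_number(pixel_size_nm) && pixel_size_nm > 0,
             "`pixel_size_nm` must be a positive number")
  structure(list(data = data, pixel_size_nm = pixel_size_nm,
                 channel = as.character(channel)),
            class = "micro_image")
}

#' @export
print.micro_image <- function(x, ...) {
  cat(sprintf("<micro_image> %d x %d px, %.1f nm/px, channel %s\n",
              nrow(x$data), ncol(x$data), x$pixel_size_nm, x$channel))
  cat(sprintf("  intensity range [%.3g, %.3g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.micro_image <- function(x) dim(x$data)

# 1-D Gaussian kernel, truncated at +-5 sigma, normalized to sum 1
gaussian_kernel <- function(sigma) {
  check_that(is_number(sigma) && sigma > 0, "`sigma` must be > 0")
  r <- ceiling(5 * sigma)
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# 1-D linear convolution of each column of `m` with a centered
# odd-length kernel, zero padding outside the support. Short kernels go
# through stats::filter (C loop); long kernels through FFT (exact linear
# convolution on a zero-padded length).
conv_columns <- function(m, k) {
  r <- (length(k) - 1) / 2
  n <- nrow(m)
  if (length(k) <= 64) {
    padded <- rbind(matrix(0, r, ncol(m)), m, matrix(0, r, ncol(m)))
    out <- stats::filter(padded, k, sides = 2)
    matrix(out[(r + 1):(r + n), ], nrow = n)
  } else {
    nfull <- n + length(k) - 1
    kf <- stats::fft(c(k, rep(0, nfull - length(k))))
    mf <- stats::mvfft(rbind(m, matrix(0, nfull - n, ncol(m))))
    full <- Re(stats::mvfft(mf * kf, inverse = TRUE)) / nfull
    matrix(full[(r + 1):(r + n), ], nrow = n)
  }
}

# Separable Gaussian blur with zero padding (linear convolution
# restricted to the original support, kernel truncated at +-5 sigma):
# signal further than 5 sigma from an edge is conserved exactly.
gaussian_blur <- function(img, sigma) {
  if (sigma == 0) return(img)
  k <- gaussian_kernel(sigma)
  t(conv_columns(t(conv_columns(img, k)), k))
}

# Vectorized bilinear sampling at fractional (row, col) coordinates.
# Coordinates outside [1, n] are an error (callers validate footprints).
bilinear_sample <- function(img, rows, cols) {
  nr <- nrow(img); nc <- ncol(img)
  check_that(all(rows >= 1 & rows <= nr & cols >= 1 & cols <= nc),
             "sample coordinates outside image")
  r0 <- pmin(floor(rows), nr - 1L); c0 <- pmin(floor(cols), nc - 1L)
  fr <- rows - r0; fc <- cols - c0
  v00 <- img[cbind(r0, c0)]
  v10 <- img[cbind(r0 + 1, c0)]
  v01 <- img[cbind(r0, c0 + 1)]
  v11 <- img[cbind(r0 + 1, c0 + 1)]
  (1 - fr) * (1 - fc) * v00 + fr * (1 - fc) * v10 +
    (1 - fr) * fc * v01 + fr * fc * v11
}

#' Write / read images as 32-bit float TIFF
#'
#' Multi-channel or multi-frame stacks are written one page per matrix.
#' The TIFF layer stores samples on a \[0, 1\] scale, so intensities are
#' mapped affinely as `(value + 32768) / 65536` on write and inverted on
#' read; photon-count images (including slightly negative values from
#' read noise) round-trip within float32 precision.
#'
#' @param images a `micro_image` or list of `micro_image`s (pages)
#' @param path output path
#' @return `write_micro_image()` returns `path` invisibly;
#'   `read_micro_image()` returns a list of `micro_image`s
#' @export
write_micro_image <- function(images, path) {
  if (inherits(images, "micro_image")) images <- list(images)
  check_that(all(vapply(images, inherits, TRUE, "micro_image")),
             "`images` must be micro_image objects")
  rng <- range(vapply(images, function(im) range(im$data), numeric(2)))
  check_that(rng[1] > -32768 && rng[2] < 32768,
             "intensities outside the storable range (-32768, 32768)")
  pages <- lapply(images, function(im) (im$data + 32768) / 65536)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_micro_image
#' @param pixel_size_nm,channel metadata to attach on read (TIFF pages do
#'   not carry them)
#' @export
read_micro_image <- function(path, pixel_size_nm = 137, channel = "GFP") {
  check_that(file.exists(path), "TIFF not found: %s", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    micro_image(p * 65536 - 32768, pixel_size_nm = pixel_size_nm,
                channel = channel)
  })
}

#' Write / read a ground-truth sidecar file
#'
#' Plain-text key-value sidecar (one `key<TAB>value` pair per line)
#' recording the generating spec and derived truth of a simulation, so
#' that simulated datasets on disk stay self-describing.
#'
#' @param truth named list of scalars
#' @param path output path
#' @export
write_ground_truth <- function(truth, path) {
  check_that(is.list(truth) && length(names(truth)) == length(truth),
             "`truth` must be a fully named list")
  flat <- unlist(truth)
  writeLines(paste(names(flat), vapply(flat, format, "", digits = 17),
                   sep = "\t"), path)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  vals <- lapply(parts, function(p) {
    v <- suppressWarnings(as.numeric(p[2]))
    if (is.na(v) && p[2] != "NA") p[2] else v
  })
  setNames(vals, vapply(parts, `[`, "", 1))
}
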