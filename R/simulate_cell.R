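# Synthetic equatorial confocal sections with known ground truth.
#
# Forward model: a cell of radius R (px) centred in the field carries a
# fraction f of the total signal on a thin membrane annulus (1 px wide
# before blur -- the bilayer is sub-resolution, so the observed peak width
# is set by the PSF) and the remainder (1 - f) uniformly in the cytosolic
# disk. The scene is blurred with a Gaussian PSF, a constant background is
# added, and detector noise is applied after the blur: Poisson on
# (signal + background) photons, then additive Gaussian read noise.

#' Specify a synthetic equatorial cell
#'
#' Defaults emulate a confocal recording at 137 nm pixels of a cell of
#' ~11 um diameter. The linescan geometry (a 100 px scan entering the cell
#' along +col through the cell centre, starting `linescan_offset` px
#' outside the membrane) is part of the spec so the generator can report
#' where the analysis should sample.
#'
#' @param image_height,image_width image size in pixels
#' @param pixel_size_nm physical pixel size (nm)
#' @param cell_center `c(row, col)` of the cell centre (px)
#' @param cell_radius cell radius (px)
#' @param membrane_thickness pre-blur annulus thickness (px)
#' @param total_signal total cell-associated photons (membrane + cytosol)
#' @param membrane_fraction fraction of `total_signal` on the membrane,
#'   in `[0, 1]`
#' @param background_level uniform background (photons/px)
#' @param psf_sigma Gaussian PSF standard deviation (px), > 0
#' @param photon_noise apply Poisson noise?
#' @param read_noise_sigma Gaussian read noise SD (photons), >= 0
#' @param linescan_offset px between scan start and the membrane
#' @param seed integer seed (required; generators never touch the global
#'   RNG state implicitly)
#' @return an object of class `cell_spec`
#' @export
cell_spec <- function(image_height = 300, image_width = 300,
                      pixel_size_nm = 137,
                      cell_center = c(150, 150), cell_radius = 40,
                      membrane_thickness = 1,
                      total_signal = 2e6, membrane_fraction = 0.6,
                      background_level = 10, psf_sigma = 1,
                      photon_noise = TRUE, read_noise_sigma = 2,
                      linescan_offset = 30, seed) {
  spec <- list(
    image_height = image_height, image_width = image_width,
    pixel_size_nm = pixel_size_nm,
    cell_center = cell_center, cell_radius = cell_radius,
    membrane_thickness = membrane_thickness,
    total_signal = total_signal, membrane_fraction = membrane_fraction,
    background_level = background_level, psf_sigma = psf_sigma,
    photon_noise = isTRUE(photon_noise), read_noise_sigma = read_noise_sigma,
    linescan_offset = linescan_offset, seed = as.integer(seed))
  class(spec) <- "cell_spec"
  validate_cell_spec(spec)
  spec
}

validate_cell_spec <- function(spec) {
  check_that(is_number(spec$membrane_fraction) &&
               spec$membrane_fraction >= 0 && spec$membrane_fraction <= 1,
             "`membrane_fraction` must lie in [0, 1], got %s",
             format(spec$membrane_fraction))
  check_that(is_number(spec$psf_sigma) && spec$psf_sigma > 0,
             "`psf_sigma` must be > 0")
  check_that(is_number(spec$total_signal) && spec$total_signal > 0,
             "`total_signal` must be > 0")
  check_that(is_number(spec$background_level) && spec$background_level >= 0,
             "`background_level` must be >= 0")
  check_that(is_number(spec$read_noise_sigma) && spec$read_noise_sigma >= 0,
             "`read_noise_sigma` must be >= 0")
  check_that(is_count(spec$seed + 1), "`seed` must be a single integer")
  r <- spec$cell_radius; ctr <- spec$cell_center
  pad <- ceiling(5 * spec$psf_sigma) + spec$membrane_thickness
  # linescan enters along +col: require the 110 px approach margin there
  margin_scan <- ctr[2] - r
  if (margin_scan < 110) {
    abort(sprintf(
      "cell does not fit: linescan-side margin is %.1f px (cell edge at col %.1f), need >= 110 px for the 100 px scan plus cytosol window",
      margin_scan, ctr[2] - r))
  }
  fits <- ctr[1] - r - pad >= 1 && ctr[1] + r + pad <= spec$image_height &&
    ctr[2] + r + pad <= spec$image_width
  if (!fits) {
    abort(sprintf(
      "cell does not fit: centre (%g, %g), radius %g + blur pad %g px exceeds the %d x %d image",
      ctr[1], ctr[2], r, pad, spec$image_height, spec$image_width))
  }
  invisible(spec)
}

# Default linescan geometry implied by a cell_spec: anchor on the +col
# approach side, direction outside -> inside.
cell_linescan_geometry <- function(spec) {
  list(anchor = c(spec$cell_center[1],
                  spec$cell_center[2] - spec$cell_radius - spec$linescan_offset),
       direction = c(0, 1),
       membrane_index = spec$linescan_offset + 1)
}

# Rasterization is anti-aliased: mask coverage is evaluated on a grid
# MASK_SUBSAMPLE times finer than the rendering grid and summed into
# rendering pixels, so partial pixels at the annulus and disk boundaries
# carry fractional weight at every rendering scale. Without this the
# 1-px annulus aliases badly at standard resolution and the
# standard-vs-oversampled forward models disagree by several percent.
MASK_SUBSAMPLE <- 4L

# Fractional subpixel coverage of the annulus and disk, anti-aliased
# linearly along the radial direction (h = subpixel edge): a subpixel at
# radial distance d covers the ring in proportion to the overlap of
# [d - h/2, d + h/2] with [R - t/2, R + t/2]. Weight sums converge to
# the analytic areas as O(h^2), so densities stay consistent across
# rendering scales while weight-sum normalization keeps the rendered
# total exactly equal to total_signal.
ring_coverage <- function(d, radius, thickness, h) {
  pmin(pmax((thickness / 2 - abs(d - radius)) / h + 0.5, 0), 1)
}

disk_coverage <- function(d, radius, h) {
  pmin(pmax((radius - d) / h + 0.5, 0), 1)
}

# total coverage-weight sums over the full fine grid;
# purely geometric, cached per (geometry, fine scale)
cell_mask_counts <- function(spec, scale_eff) {
  key <- paste("counts", spec$image_height, spec$image_width,
               spec$cell_center[1], spec$cell_center[2],
               spec$cell_radius, spec$membrane_thickness, scale_eff,
               sep = "_")
  cache_get_or(key, function() {
    nr <- spec$image_height * scale_eff
    nc <- spec$image_width * scale_eff
    h <- 1 / scale_eff
    cc2 <- ((seq_len(nc) - 0.5) / scale_eff + 0.5 - spec$cell_center[2])^2
    ring <- 0; disk <- 0
    for (chunk in split(seq_len(nr), ceiling(seq_len(nr) / 256))) {
      rr2 <- ((chunk - 0.5) / scale_eff + 0.5 - spec$cell_center[1])^2
      d <- sqrt(outer(rr2, cc2, "+"))
      ring <- ring + sum(ring_coverage(d, spec$cell_radius,
                                       spec$membrane_thickness, h))
      disk <- disk + sum(disk_coverage(d, spec$cell_radius, h))
    }
    list(ring = ring, disk = disk)
  })
}

# Noise-free blurred signal (no background) rendered on a sub-grid.
# `rows`/`cols` are original-pixel coordinate bounds c(lo, hi); the patch
# is padded by the kernel support before blurring so the crop is an exact
# linear convolution of the full scene.
render_cell_signal <- function(spec, scale = 1,
                               rows = c(1, spec$image_height),
                               cols = c(1, spec$image_width)) {
  sub <- MASK_SUBSAMPLE
  scale_eff <- scale * sub
  counts <- cell_mask_counts(spec, scale_eff)
  pad <- ceiling(5 * spec$psf_sigma) + 1
  # rendering-pixel index range covering [lo, hi] plus the blur pad
  px_idx <- function(lo, hi, n) {
    i0 <- max(1L, floor((lo - pad - 0.5) * scale + 0.5))
    i1 <- min(n * scale, ceiling((hi + pad - 0.5) * scale + 0.5))
    i0:i1
  }
  ri <- px_idx(rows[1], rows[2], spec$image_height)
  ci <- px_idx(cols[1], cols[2], spec$image_width)
  # fine-grid subpixels of the selected rendering pixels
  fine <- function(idx) {
    k <- rep((idx - 1) * sub, each = sub) + seq_len(sub)
    (k - 0.5) / scale_eff + 0.5
  }
  rr2 <- (fine(ri) - spec$cell_center[1])^2
  cc2 <- (fine(ci) - spec$cell_center[2])^2
  d <- sqrt(outer(rr2, cc2, "+"))
  f <- spec$membrane_fraction
  ring_mass <- if (counts$ring > 0) f * spec$total_signal / counts$ring else 0
  disk_mass <- if (counts$disk > 0) (1 - f) * spec$total_signal / counts$disk else 0
  h <- 1 / scale_eff
  m <- ring_mass * ring_coverage(d, spec$cell_radius,
                                 spec$membrane_thickness, h) +
    disk_mass * disk_coverage(d, spec$cell_radius, h)
  # optics act on the continuous scene, the detector integrates after:
  # blur on the fine grid, then bin into rendering pixels. Binning along
  # one axis commutes with convolution along the other, so each axis is
  # blurred at fine spacing and binned immediately to keep the second
  # pass cheap.
  # rasterizing at fine spacing h implicitly convolves the scene with a
  # box of variance h^2/12 (h = 1 fine px); shrink the Gaussian by that
  # variance so the total blur matches the continuum PSF at every scale
  k <- gaussian_kernel(sqrt((spec$psf_sigma * scale_eff)^2 - 1 / 12))
  bin1 <- function(x) rowsum(x, rep(seq_len(nrow(x) / sub), each = sub))
  m <- bin1(conv_columns(m, k))
  m <- t(bin1(conv_columns(t(m), k)))
  list(signal = m, row_index = ri, col_index = ci, scale = scale)
}

# sample a width-averaged linescan from a rendered (possibly oversampled)
# signal patch; anchor/direction in original-pixel coordinates.
# An oversampled render is first integrated over 1 x 1 px detector areas
# (centered boxcar) so its samples measure the same quantity as
# standard-resolution pixels, just computed on a finer grid.
sample_rendered_linescan <- function(render, anchor, direction,
                                     length_px = 100, width = 5) {
  s <- render$scale
  if (s > 1) {
    # trapezoid weights = exact 1-px integral of the linear interpolant
    box <- c(0.5, rep(1, s - 1), 0.5) / s
    r <- (length(box) - 1) / 2
    band <- function(n) {
      d <- outer(seq_len(n), seq_len(n), "-")
      m <- matrix(0, n, n)
      sel <- abs(d) <= r
      m[sel] <- box[d[sel] + r + 1]
      m
    }
    render$signal <- band(nrow(render$signal)) %*% render$signal %*%
      t(band(ncol(render$signal)))
    # detector pixels sum photons over their area; the boxcar above is a
    # mean over s^2 subpixel masses, so the 1-px integral needs s^2
    render$signal <- render$signal * s^2
  }
  dir <- direction / sqrt(sum(direction^2))
  perp <- c(-dir[2], dir[1])
  offs <- seq(-(width - 1) / 2, (width - 1) / 2)
  k <- seq_len(length_px) - 1
  pos_r <- outer(k, offs, function(a, b) anchor[1] + a * dir[1] + b * perp[1])
  pos_c <- outer(k, offs, function(a, b) anchor[2] + a * dir[2] + b * perp[2])
  # map original-px coordinates onto the patch grid
  s <- render$scale
  gr <- (pos_r - 0.5) * s + 0.5 - (render$row_index[1] - 1)
  gc <- (pos_c - 0.5) * s + 0.5 - (render$col_index[1] - 1)
  vals <- bilinear_sample(render$signal, as.vector(gr), as.vector(gc))
  rowMeans(matrix(vals, nrow = length_px))
}

#' Forward-model periphery/cytosol ratio
#'
#' Computes the periphery/cytosol ratio implied by a cell spec from a
#' noise-free render of the forward model: the default linescan is
#' sampled, normalized to its peak, and the cytosol level is averaged over
#' the five samples starting 10 px interior to the peak. With
#' `oversample = 10` this is the reference value recorded in the ground
#' truth (and the oracle the standard-resolution estimator is validated
#' against). When `membrane_fraction = 1` there is no cytosolic pool and
#' the ratio is `Inf` by definition.
#'
#' @param spec a [cell_spec()]
#' @param oversample integer rendering oversampling factor (>= 1)
#' @return the ratio (dimensionless, >= 1), possibly `Inf`
#' @export
forward_model_ratio <- function(spec, oversample = 10) {
  validate_cell_spec(spec)
  if (spec$membrane_fraction >= 1) return(Inf)
  key <- paste("ratio", spec$image_height, spec$image_width,
               spec$cell_center[1], spec$cell_center[2], spec$cell_radius,
               spec$membrane_thickness, spec$membrane_fraction,
               spec$psf_sigma, spec$linescan_offset, oversample, sep = "_")
  cache_get_or(key, function() {
    geom <- cell_linescan_geometry(spec)
    rows <- spec$cell_center[1] + c(-3, 3)
    cols <- c(geom$anchor[2], geom$anchor[2] + 99)
    render <- render_cell_signal(spec, scale = oversample,
                                 rows = rows, cols = cols)
    vals <- sample_rendered_linescan(render, geom$anchor, geom$direction)
    # first-occurrence peak with a relative tie tolerance: for f = 0 the
    # interior plateau is constant up to convolution rounding error, and
    # the peak must resolve to the first plateau sample, not wherever the
    # 1e-15 jitter happens to culminate
    peak <- which(vals >= max(vals) * (1 - 1e-9))[1]
    check_that(peak + 14 <= length(vals),
               "cytosol window exceeds the forward-model trace (peak at %d)",
               peak)
    cyt <- mean(vals[(peak + 10):(peak + 14)])
    check_that(cyt > 0, "forward-model cytosol level is not positive")
    vals[peak] / cyt
  })
}

#' Simulate an equatorial confocal section
#'
#' Renders the forward model described in [cell_spec()], applies detector
#' noise after the PSF blur, and returns the image together with full
#' ground truth (membrane fraction, the analytic periphery/cytosol ratio
#' from a 10x-oversampled noise-free render, and the linescan geometry).
#'
#' @param spec a [cell_spec()]
#' @return a list of class `simulated_cell` with elements `image`
#'   (a [micro_image()]) and `truth` (named list)
#' @examples
#' sim <- simulate_equatorial_cell(cell_spec(membrane_fraction = 0.6, seed = 1))
#' sim$truth$analytic_ratio
#' @export
simulate_equatorial_cell <- function(spec) {
  validate_cell_spec(spec)
  render <- render_cell_signal(spec, scale = 1)
  signal <- render$signal
  img <- signal + spec$background_level
  img <- with_seed(spec$seed, {
    out <- img
    if (spec$photon_noise) {
      out <- matrix(rpois(length(out), lambda = out),
                    nrow = nrow(out))
    }
    if (spec$read_noise_sigma > 0) {
      out <- out + matrix(rnorm(length(out), sd = spec$read_noise_sigma),
                          nrow = nrow(out))
    }
    out
  })
  geom <- cell_linescan_geometry(spec)
  truth <- list(
    membrane_fraction = spec$membrane_fraction,
    analytic_ratio = forward_model_ratio(spec, oversample = 10),
    total_signal = spec$total_signal,
    background_level = spec$background_level,
    anchor_row = geom$anchor[1], anchor_col = geom$anchor[2],
    direction_row = geom$direction[1], direction_col = geom$direction[2],
    membrane_index = geom$membrane_index,
    seed = spec$seed)
  structure(list(image = micro_image(img, spec$pixel_size_nm, "GFP"),
                 signal = signal, truth = truth, spec = spec),
            class = "simulated_cell")
}
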