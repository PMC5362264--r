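# Synthetic two-channel membrane-sheet images: a membrane-marker (blue)
# channel that delineates the sheet footprint and a protein (green)
# channel whose intensity above background is proportional to the bound
# protein density. Emulates epifluorescence recordings of unroofed cells
# at 64.5 nm pixels.

#' Specify a synthetic membrane sheet
#'
#' @param image_height,image_width image size (px)
#' @param pixel_size_nm physical pixel size (nm)
#' @param sheet_center `c(row, col)` centre of the rectangular footprint
#' @param sheet_halfwidth `c(row, col)` half-extents of the footprint; the
#'   footprint must admit a 30 x 30 px quantification ROI
#' @param density mean bound-protein signal per footprint pixel (photons)
#' @param blue_level membrane-marker signal per footprint pixel (photons)
#' @param background_green,background_blue uniform backgrounds (photons/px)
#' @param photon_noise apply Poisson noise?
#' @param read_noise_sigma Gaussian read noise SD (photons)
#' @param seed integer seed (required)
#' @return an object of class `sheet_spec`
#' @export
sheet_spec <- function(image_height = 120, image_width = 120,
                       pixel_size_nm = 64.5,
                       sheet_center = c(60, 60),
                       sheet_halfwidth = c(35, 35),
                       density = 100, blue_level = 500,
                       background_green = 20, background_blue = 50,
                       photon_noise = TRUE, read_noise_sigma = 2, seed) {
  spec <- list(image_height = image_height, image_width = image_width,
               pixel_size_nm = pixel_size_nm,
               sheet_center = sheet_center, sheet_halfwidth = sheet_halfwidth,
               density = density, blue_level = blue_level,
               background_green = background_green,
               background_blue = background_blue,
               photon_noise = isTRUE(photon_noise),
               read_noise_sigma = read_noise_sigma, seed = as.integer(seed))
  class(spec) <- "sheet_spec"
  validate_sheet_spec(spec)
  spec
}

validate_sheet_spec <- function(spec) {
  check_that(is_number(spec$density) && spec$density >= 0,
             "`density` must be >= 0")
  check_that(is_count(spec$seed + 1), "`seed` must be a single integer")
  ext <- 2 * spec$sheet_halfwidth + 1
  if (any(ext < 30)) {
    abort(sprintf(
      "sheet footprint %d x %d px is smaller than the 30 x 30 px quantification ROI",
      ext[1], ext[2]))
  }
  fits <- spec$sheet_center[1] - spec$sheet_halfwidth[1] >= 1 &&
    spec$sheet_center[1] + spec$sheet_halfwidth[1] <= spec$image_height &&
    spec$sheet_center[2] - spec$sheet_halfwidth[2] >= 1 &&
    spec$sheet_center[2] + spec$sheet_halfwidth[2] <= spec$image_width
  check_that(fits, "sheet footprint does not fit inside the %d x %d image",
             spec$image_height, spec$image_width)
  invisible(spec)
}

#' Simulate a two-channel membrane-sheet image
#'
#' @param spec a [sheet_spec()]
#' @return a list of class `simulated_sheet` with `green` and `blue`
#'   [micro_image()]s and a `truth` list (density, footprint, backgrounds)
#' @export
simulate_membrane_sheet <- function(spec) {
  validate_sheet_spec(spec)
  footprint <- matrix(0, spec$image_height, spec$image_width)
  rr <- (spec$sheet_center[1] - spec$sheet_halfwidth[1]):
    (spec$sheet_center[1] + spec$sheet_halfwidth[1])
  cc <- (spec$sheet_center[2] - spec$sheet_halfwidth[2]):
    (spec$sheet_center[2] + spec$sheet_halfwidth[2])
  footprint[rr, cc] <- 1
  green <- spec$density * footprint + spec$background_green
  blue <- spec$blue_level * footprint + spec$background_blue
  noisy <- with_seed(spec$seed, {
    lapply(list(green = green, blue = blue), function(ch) {
      out <- ch
      if (spec$photon_noise) {
        out <- matrix(rpois(length(out), out), nrow = nrow(out))
      }
      if (spec$read_noise_sigma > 0) {
        out <- out + matrix(rnorm(length(out), sd = spec$read_noise_sigma),
                            nrow = nrow(out))
      }
      out
    })
  })
  truth <- list(density = spec$density,
                background_green = spec$background_green,
                background_blue = spec$background_blue,
                footprint_rows = range(rr), footprint_cols = range(cc),
                roi_center = spec$sheet_center, seed = spec$seed)
  structure(list(
    green = micro_image(noisy$green, spec$pixel_size_nm, "GFP"),
    blue = micro_image(noisy$blue, spec$pixel_size_nm, "TMA-DPH"),
    truth = truth, spec = spec), class = "simulated_sheet")
}
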