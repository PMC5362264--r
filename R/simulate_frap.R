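# Synthetic FRAP recordings. The recovery after the bleach step follows
# the empirical hyperbola y(t) = offset + M * t / (t + t_half) on the
# normalized intensity scale, with t = 0 at the first post-bleach frame.
# The generator emits both the normalized trace and raw detector-scale
# frames (pre-bleach frames included) so the normalization step can be
# validated by round trip.

#' Specify a synthetic FRAP recording
#'
#' Defaults emulate recordings at 1.2 Hz for 113 s with three pre-bleach
#' frames, 0.414 um pixels and a 7 x 7 px bleach ROI.
#'
#' @param frame_rate acquisition rate (Hz)
#' @param duration post-bleach recording duration (s); frames are taken at
#'   `t_k = k / frame_rate` for `k = 0 .. floor(duration * frame_rate)`
#' @param n_prebleach number of pre-bleach frames
#' @param pixel_size_um pixel size (um)
#' @param bleach_roi_edge_px bleach ROI edge (px)
#' @param true_offset normalized intensity immediately after the bleach
#' @param true_recovery maximal recovery M (normalized);
#'   `true_offset + true_recovery` must not exceed 1
#' @param true_t_half half time of recovery (s), > 0
#' @param noise_sigma additive Gaussian noise SD on the normalized scale
#' @param prebleach_intensity,background raw detector-scale pre-bleach
#'   plateau and background used for the emitted raw frames
#' @param seed integer seed (required)
#' @return an object of class `frap_spec`
#' @export
frap_spec <- function(frame_rate = 1.2, duration = 113, n_prebleach = 3,
                      pixel_size_um = 0.414, bleach_roi_edge_px = 7,
                      true_offset = 0.2, true_recovery = 0.6,
                      true_t_half = 8, noise_sigma = 0.05,
                      prebleach_intensity = 1000, background = 50, seed) {
  spec <- list(frame_rate = frame_rate, duration = duration,
               n_prebleach = as.integer(n_prebleach),
               pixel_size_um = pixel_size_um,
               bleach_roi_edge_px = bleach_roi_edge_px,
               true_offset = true_offset, true_recovery = true_recovery,
               true_t_half = true_t_half, noise_sigma = noise_sigma,
               prebleach_intensity = prebleach_intensity,
               background = background, seed = as.integer(seed))
  class(spec) <- "frap_spec"
  validate_frap_spec(spec)
  spec
}

validate_frap_spec <- function(spec) {
  check_that(is_number(spec$true_t_half) && spec$true_t_half > 0,
             "`true_t_half` must be > 0")
  check_that(is_number(spec$true_offset) && spec$true_offset >= 0,
             "`true_offset` must be >= 0")
  check_that(spec$true_offset + spec$true_recovery <= 1,
             "`true_offset + true_recovery` must be <= 1 (recovery cannot exceed the pre-bleach level)")
  check_that(is_number(spec$noise_sigma) && spec$noise_sigma >= 0,
             "`noise_sigma` must be >= 0")
  check_that(spec$n_prebleach >= 1, "`n_prebleach` must be >= 1")
  check_that(is_number(spec$frame_rate) && spec$frame_rate > 0,
             "`frame_rate` must be > 0")
  check_that(spec$prebleach_intensity > spec$background,
             "`prebleach_intensity` must exceed `background`")
  check_that(is_count(spec$seed + 1), "`seed` must be a single integer")
  invisible(spec)
}

#' Physical bleach-ROI edge length
#'
#' @param spec a [frap_spec()]
#' @return edge length in micrometres (`bleach_roi_edge_px * pixel_size_um`)
#' @examples
#' bleach_roi_edge_um(frap_spec(seed = 1))  # 7 px x 0.414 um = 2.898 um
#' @export
bleach_roi_edge_um <- function(spec) {
  check_that(inherits(spec, "frap_spec"), "`spec` must be a frap_spec")
  spec$bleach_roi_edge_px * spec$pixel_size_um
}

# hyperbolic recovery model shared by the generator and the fitter
hyperbola_model <- function(t, offset, recovery, t_half) {
  offset + recovery * t / (t + t_half)
}

#' Simulate a FRAP trace
#'
#' @param spec a [frap_spec()]
#' @return a list of class `simulated_frap` with elements `trace` (a
#'   normalized [recovery_trace()]), `raw` (tibble of detector-scale
#'   frames: `frame`, `phase`, `time`, `intensity`), and `truth`
#' @export
simulate_frap_trace <- function(spec) {
  validate_frap_spec(spec)
  k <- 0:floor(spec$duration * spec$frame_rate)
  t_post <- k / spec$frame_rate
  y_true <- hyperbola_model(t_post, spec$true_offset, spec$true_recovery,
                            spec$true_t_half)
  n_pre <- spec$n_prebleach
  norm_all <- with_seed(spec$seed, {
    c(rep(1, n_pre), y_true) +
      rnorm(n_pre + length(y_true), sd = spec$noise_sigma)
  })
  raw <- spec$background +
    (spec$prebleach_intensity - spec$background) * norm_all
  # pre-bleach frames sit before the 500 ms bleach dead time
  t_pre <- -(n_pre:1) / spec$frame_rate - 0.5
  raw_tbl <- tibble(
    frame = seq_along(norm_all),
    phase = rep(c("prebleach", "postbleach"), c(n_pre, length(y_true))),
    time = c(t_pre, t_post),
    intensity = raw)
  trace <- recovery_trace(t_post, norm_all[-seq_len(n_pre)],
                          prebleach_mean = mean(norm_all[seq_len(n_pre)]),
                          background = 0, n_prebleach = n_pre)
  truth <- list(offset = spec$true_offset, recovery = spec$true_recovery,
                t_half = spec$true_t_half, noise_sigma = spec$noise_sigma,
                n_frames = length(y_true), seed = spec$seed)
  structure(list(trace = trace, raw = raw_tbl, truth = truth, spec = spec),
            class = "simulated_frap")
}
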