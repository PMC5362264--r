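# shared fixtures: small specs and toy data built in code

# fast noiseless cell spec (default geometry)
quiet_cell <- function(f, seed = 1, ...) {
  cell_spec(membrane_fraction = f, photon_noise = FALSE,
            read_noise_sigma = 0, seed = seed, ...)
}

# toy measurement table: two conditions x two replicates, exact ratios 2 and 0.5
toy_fractionation_table <- function() {
  tibble::tibble(
    condition = rep(c("wt", "mut"), each = 4),
    replicate = rep(rep(1:2, each = 2), 2),
    compartment = rep(c("membrane", "cytosol"), 4),
    intensity = c(80, 40, 100, 50, 20, 40, 30, 60))
}

# closed-form linescan samples on the linear ramp image z = a*row + b*col:
# bilinear interpolation reproduces a linear function exactly, and the
# 5-px perpendicular average of a linear field equals its centre value
ramp_image <- function(n = 200, a = 2, b = 3) {
  outer(seq_len(n), seq_len(n), function(r, c) a * r + b * c)
}

expected_ramp_linescan <- function(anchor, direction, a = 2, b = 3,
                                   length_px = 100) {
  dir <- direction / sqrt(sum(direction^2))
  k <- seq_len(length_px) - 1
  a * (anchor[1] + k * dir[1]) + b * (anchor[2] + k * dir[2])
}
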