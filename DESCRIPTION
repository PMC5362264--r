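Package: memtarget
Title: Quantifying Electrostatic Plasma Membrane Targeting of SNARE Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how basic residues flanking the
    palmitoylated cysteine cluster of SNAP25/SNAP23 recruit the protein to
    the plasma membrane. Implements a residue-charge model for
    cysteine-rich-region (CRR) constructs and mutagenesis series, confocal
    linescan periphery/cytosol ratio estimation, hyperbolic FRAP
    (fluorescence recovery after photobleaching) curve fitting, and
    control-subtracted binding/band-ratio statistics, together with seeded
    synthetic-data generators (PSF-blurred equatorial cell images with
    Poisson photon and Gaussian read noise, membrane-sheet images, FRAP
    traces, measurement tables) that provide ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
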