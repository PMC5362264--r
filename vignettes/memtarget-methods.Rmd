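---
title: "Models and methods behind memtarget"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind memtarget}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
library(memtarget)
```

`memtarget` quantifies electrostatic plasma-membrane recruitment of
SNAP25/SNAP23: a residue-charge model of the cysteine-rich region (CRR),
a periphery/cytosol statistic from confocal linescans, hyperbolic FRAP
recovery fitting, and four control-subtracted ratio quantifications.
Because the raw imaging and gel data underlying such experiments are
rarely available, the package ships seeded forward models for each data
type; every estimator is validated against the exact ground truth of
those generators. This vignette records the models, the parameters that
matter, the numerical choices, and what the synthetic validation does and
does not establish.

## The residue-charge model

The nominal charge of a sequence window is (#K + #R) − (#D + #E).
Histidine is not counted: at physiological pH its charge is partial at
best, and the charge series this model serves (K→A, K→L substitutions,
and R→A in the C-terminal polybasic cluster) never manipulates histidine.
Residue numbering is 1-based throughout, so construct names like R191A or
C85 read off directly.

Windows are always explicit. The CRR of rat SNAP-25B is described in the
literature by its content — four palmitoylated cysteines (85, 88, 90,
92) flanked by four lysines on each side, with four acidic residues
upstream of the cysteines and one downstream — but not by numeric
bounds. `snap25_crr_window()` returns 70–103, the minimal window
containing exactly those residues: lysines 72, 76, 79, 83 (upstream) and
94, 96, 102, 103 (downstream), acidic residues D70, E73, E75, D80 and
D99. Eight basic versus five acidic residues give the wild-type net
charge of +3; substituting the inner four lysines (79, 83, 94, 96) or
the outer four (72, 76, 102, 103) with alanine gives −1, all eight give
−5, and exchanging the four cysteines for glycine leaves the charge
untouched. For SNAP23 the published window is residues 64–100. Any other
window must be supplied by the user — the package never guesses
coordinates.

Whole-protein composition (`charge_composition()`) reports percentages
of acidic and basic residues both raw and rounded half-up. For the
bundled 206-residue rat SNAP-25B (RefSeq NP_112253.1), 43 acidic
residues give 20.87% — the conventionally printed 21% — while 30 basic
residues give 14.56%, which truncates to the commonly quoted 14% but
rounds half-up to 15%. Both representations are returned so the caller
can see the raw value behind any printed figure; the package treats the
raw percentage as the contract.

## Synthetic equatorial cells and the linescan statistic

The image forward model is deliberately minimal: a cell of radius $R$
(default 40 px at 137 nm/px, a ~11 µm cell) centred in a 300×300 field
carries a fraction $f$ of its total signal on a membrane annulus 1 px
wide before blur — the bilayer is far below the diffraction limit, so
the observed peak width is set entirely by the PSF — and the remaining
$1-f$ uniformly in the cytosolic disk. The scene is convolved with a
Gaussian PSF (default σ = 1 px ≈ 137 nm), a constant background is
added, and detector noise is applied after the blur: Poisson on the
photon counts, then additive Gaussian read noise. Defaults
(`total_signal = 2e6` photons, background 10, read noise σ = 2) give a
cytosolic plateau of roughly 160 photons/px — a comfortably but not
unrealistically exposed 12-bit confocal frame. No instrument gain or
photon budget is published for this kind of recording, so these defaults
are a documented choice and every one of them is user-overridable.

Rendering follows detector physics more carefully than a naive
rasterizer, because the package validates its standard-resolution render
against a 10×-oversampled reference and a thin bright ring is the
worst case for aliasing:

- masks are rasterized with fractional, radially anti-aliased coverage
  weights, and normalized by the weight sum so the rendered scene
  integrates to exactly `total_signal` at any resolution;
- the PSF blur is applied on a fine sub-grid (4 sub-samples per rendered
  pixel) *before* binning into detector pixels — optics act on the
  continuous scene, the detector integrates afterwards;
- sampling at fine spacing $h$ implicitly convolves with a box of
  variance $h^2/12$; the Gaussian kernel is narrowed by that amount so
  the effective blur matches the continuum PSF at every scale;
- the oversampled reference reports 1-px detector-area integrals (not
  point samples) along the linescan, so both renders measure the same
  physical quantity.

With these choices the standard and 10×-oversampled renders agree on the
periphery/cytosol ratio to ~0.5% across membrane fractions, and the
noise-free estimate lands within 2% of the reference. At $f = 1$ there
is no cytosolic pool and the forward-model ratio is reported as `Inf`;
any finite value there would be an artefact of Gaussian tails.

The linescan statistic follows the manual confocal procedure: 100
samples at 1 px spacing along a direction perpendicular to the membrane
(outside → inside), each averaged over 5 px across the scan, bilinearly
interpolated for oblique directions. Traces are background-corrected
(default background: the mean of the first 10 samples, which lie outside
the cell in the standard geometry), normalized to the membrane peak
(global maximum, first occurrence on ties), aligned on their peaks
(median peak index; indices supported by fewer than 80% of traces are
dropped) and averaged. The cytosolic level is the mean over indices
peak+10..peak+14 — five pixels starting 10 px interior to the peak, the
interior side being defined by the stored scan direction — and the ratio
is peak/cytosol = 1/cytosol for a normalized trace. `cell_ratio()`, the
convenience wrapper for simulated cells, restricts the peak search to
±10 px around the known membrane position: this mirrors the operator
anchoring the scan on the visible membrane, and matters for cells
without a membrane pool, where a flat noisy trace would otherwise put
the "peak" arbitrarily deep in the cytosol. Summaries are two-level, as
in the imaging experiments they emulate: cells are averaged within an
imaging day, conditions are summarized as mean ± SEM across day means.

The generator emulates one cell per field, perfect radial symmetry, a
flat cytosol and a spatially uniform background. It does not emulate
neighbouring cells, organelles or vesicular structures, membrane
ruffling, depth-dependent blur, or operator variability in scan
placement. Passing tests therefore establish that the estimator chain is
correct and calibrated on its own model assumptions — not that those
assumptions capture every real PC12 cell; on real data the manual
anchor/direction annotations carry that burden.

## FRAP model and fitting

Recovery traces are normalized to the pre-bleach level:
background-subtracted intensities divided by the background-subtracted
mean of (by default three) pre-bleach frames. Time zero is the first
post-bleach frame; the ~500 ms bleach step is dead time, not fitted,
which makes the model well-posed (the fitted curve passes through
`offset` at $t = 0$). The model is the empirical hyperbola

$$y(t) = \mathrm{offset} + M \cdot \frac{t}{t + t_{1/2}},$$

fitted by ordinary (unweighted) least squares with Levenberg–Marquardt
(`minpack.lm::nlsLM`). Starting values: offset = first value, $M$ = last
− first, $t_{1/2}$ = first time the trace exceeds offset + $M/2$
(fallback: mid-time). Box constraints keep the optimizer out of
degenerate plateaus: offset and $M$ in $[0, 1.5]$, $t_{1/2}$ in
$(0, 10\,t_{\max}]$; whether the original analyses constrained the
offset is not documented anywhere, so the bounds are a package choice,
stated here. Non-convergence is flagged on the returned object, never
silent; an all-constant trace is rejected because $t_{1/2}$ is then
unidentifiable. Per-timepoint SDs from trace averaging are reported but
not used as weights, matching the unweighted original procedure.

One calibration fact worth knowing: at the default acquisition
conditions (1.2 Hz for 113 s → 136 post-bleach frames) with noise
σ = 0.05 and $t_{1/2} = 8$ s, the Cramér–Rao bound implies a median
relative error of ~10% in $t_{1/2}$ for *any* unbiased estimator — the
per-trace fit is information-limited, not implementation-limited. This
is why recovery experiments average 7–15 sheets per condition before
fitting; `average_recovery()` + `fit_hyperbola()` reproduces that
practice, and per-trace fitting remains available for robustness
studies.

## Ratio quantifiers

All four quantifiers consume long-format tables (condition, replicate,
compartment, intensity; liposome tables add a lipid-mix column):

- *Fractionation*: membrane/cytosol per replicate; replicates with zero
  cytosol signal are excluded with a warning and recorded on the result.
  Per-replicate ratios (then averaged) are the default reading; whether
  the original blots were ratioed per replicate or on summed intensities
  is not stated, and summing is a one-line alternative on the table.
- *Membrane sheets*: mean green intensity in 30×30 px ROIs, background
  subtracted, gated on the membrane-marker (blue) channel exceeding a
  user threshold (the original screening was visual; a fixed threshold
  is the reproducible stand-in). Condition means are divided by the
  wild-type mean, so the reference is exactly 1 by construction.
- *Palmitoylation*: Cy5(clicked palmitate)/GFP per replicate; a
  cysteine-free control with no clickable palmitate gives exactly 0.
- *Liposome binding*: specific = bait − GST control, matched by
  replicate index within a lipid mix (default; propagates replicate
  variance) or against the mix-wise control mean. Negative specific
  binding is retained and flagged, never clipped — truncation at zero
  would bias condition means upward.

The table generator draws a shared lognormal loading factor per
replicate (cancels in any within-replicate ratio) and applies the stated
CV multiplicatively to the ratio's numerator, so the replicate ratio is
an unbiased estimator of the true ratio. This matters for the
Monte-Carlo calibration tests: with independent noise on both
compartments, E[num/den] exceeds the true ratio by ≈ CV², which at
CV = 0.1 is the same order as the 1% tolerance those tests use.

## Statistics

Condition summaries report mean and SEM (sample SD, $n-1$). Pairwise
comparisons against a designated reference use the two-sided Welch
(unequal-variance) t-test — the sources say only "t-test", and Welch is
the safer default; Student's pooled test is a switch. Star coding is a
pure function of p with half-open intervals: `***` p < 0.001, `**`
0.001 ≤ p < 0.01, `*` 0.01 ≤ p < 0.05, else `ns`. No multiple-testing
correction is applied by default, matching the per-comparison star
convention; Holm adjustment is available. Experiments across days are
treated as unpaired. The expression-independence diagnostic regresses
per-cell ratio on per-cell peak intensity (OLS slope with its t-test,
plus Pearson correlation); on simulated cells that differ only in total
signal the estimator is scale-free by construction, so this check
validates the diagnostic itself rather than the biology.

## Reproducibility and problem sizes

Every generator takes a mandatory integer seed and restores the caller's
RNG state; identical (spec, seed) pairs are bit-identical, and
`run_pipeline()` writes byte-stable outputs (no timestamps) so reruns of
one config can be verified by checksum. The validation suite uses
problem sizes chosen to exercise each property well inside a desk-scale
run: 20 cells per membrane fraction for calibration and monotonicity,
50 cells for expression independence, 100 noisy traces for FRAP
parameter recovery, n = 1000 replicates for the Monte-Carlo ratio
checks, and a compact two-condition end-to-end pipeline for the
determinism test.

## Known limitations

- The image model is 2-D, single-cell, radially symmetric; there is no
  diffusion model behind the FRAP hyperbola (it is an empirical fit, and
  $t_{1/2}$ is a comparative statistic, not a diffusion coefficient).
- Densitometry stops at integrated per-lane intensities; lane finding
  and rolling-ball background subtraction on gel images are out of
  scope.
- No automatic membrane segmentation: anchors and directions come from
  annotations or simulation ground truth, as in the manual procedure.
- TIFF pages store intensities affinely mapped into the [0, 1] sample
  range (`(value + 32768)/65536`, inverted on read), since the TIFF
  layer used here does not preserve out-of-range float samples.
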