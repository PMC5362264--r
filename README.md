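# memtarget

Quantification toolkit for studying how basic residues flanking the
palmitoylated cysteine cluster of SNAP25/SNAP23 anchor these SNAREs to the
plasma membrane. SNAP25 carries no transmembrane segment; its stable
attachment runs through palmitoylation of four cysteines (C85/C88/C90/C92
in rat SNAP-25B), and the initial membrane contact is thought to be
electrostatic, driven by a small surplus of lysines around the cysteine
cluster. `memtarget` implements the four quantitative assays used to test
that idea, plus seeded synthetic-data generators that provide ground truth
for validating every estimator end to end:

- **Residue-charge model** — net charge of the cysteine-rich region (CRR),
  computed as (#K + #R) − (#D + #E) over an explicit residue window
  (histidine not counted), with mutagenesis builders (K→A, K→L, C→G,
  arbitrary point substitutions) and per-construct charge tables.
- **Confocal linescan ratios** — 100 px, 5 px-width-averaged linescans
  perpendicular to the plasma membrane; background correction, peak
  normalization, peak alignment and averaging across cells; the
  periphery/cytosol ratio with the cytosol window at peak+10..peak+14 px;
  two-level (cells → day → condition) summaries.
- **FRAP fitting** — pre-bleach normalization and nonlinear least-squares
  fitting of the hyperbolic recovery model
  `y(t) = offset + M · t / (t + t½)`, yielding the half time of recovery,
  with broom-style `tidy()`/`glance()` and `autoplot()` methods.
- **Ratio quantifiers** — membrane/cytosol band ratios from fractionation
  tables, 30×30 px membrane-sheet ROI quantification normalized to wild
  type, palmitate(Cy5)/GFP click-label ratios, and GST-control-subtracted
  liposome binding.
- **Statistics & diagnostics** — means ± SEM, Welch t-tests with `*`/`**`/
  `***` star coding, and the expression-independence check (ratio vs peak
  intensity regression).
- **Synthetic data** — PSF-blurred equatorial cell images with Poisson +
  Gaussian detector noise at 137 nm pixels, two-channel membrane sheets,
  FRAP traces at 1.2 Hz with 3 pre-bleach frames, and long-format
  measurement tables — all seeded, all with exact ground truth.

## Worked example

```r
library(memtarget)

# charge series of the SNAP25 CRR (residues 70-103)
seq25 <- snap25b_sequence()
win   <- snap25_crr_window()
lys   <- snap25_flanking_lysines()
crr_charge_table(list(
  protein_construct("wt-SNAP25 (+3)", seq25, crr_window = win),
  protein_construct("SNAP25-1 proximal", seq25, crr_window = win,
                    mutations = mutations_k_to_a(seq25, lys$proximal)),
  protein_construct("SNAP25-5", seq25, crr_window = win,
                    mutations = mutations_k_to_a(seq25, lys$all))))
#> # A tibble: 3 × 4
#>   label             window_start window_end net_charge
#>   <chr>                    <int>      <int>      <int>
#> 1 wt-SNAP25 (+3)              70        103          3
#> 2 SNAP25-1 proximal           70        103         -1
#> 3 SNAP25-5                    70        103         -5

# simulate a cell with 60% membrane-bound signal and recover the ratio
sim <- simulate_equatorial_cell(cell_spec(membrane_fraction = 0.6, seed = 7))
cell_ratio(sim)[, c("ratio", "analytic_ratio")]
#> # A tibble: 1 × 2
#>   ratio analytic_ratio
#>   <dbl>          <dbl>
#> 1  11.7           11.5

# fit a FRAP recovery
fit <- fit_hyperbola(simulate_frap_trace(frap_spec(true_t_half = 8,
                                                   seed = 1))$trace)
glance(fit)
#> # A tibble: 1 × 6
#>   offset recovery t_half   rss     n converged
#>    <dbl>    <dbl>  <dbl> <dbl> <int> <lgl>
#> 1  0.234    0.567   8.42 0.250   136 TRUE
```

The first table reads: the wild-type CRR window (34 residues, 8 flanking
lysines vs 5 acidic residues) carries +3 elementary charges; substituting
the four inner lysines with alanine drops it to −1, all eight to −5. The
simulated cell's estimated periphery/cytosol ratio (11.7) agrees with the
forward model's analytic value (11.5); the FRAP fit recovers the true
half time of 8 s from a noisy trace to within its sampling error.

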