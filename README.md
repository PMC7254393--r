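# hrgcms

Annotation and comparative statistics for derivatized-metabolite GC–MS,
built around what accurate-mass (Orbitrap-class) spectra add over a
unit-mass instrument.

Untargeted GC–MS metabolomics identifies compounds by matching electron
ionization (EI) fragment spectra against unit-mass libraries. That match is
only a hypothesis: extracted pseudospectra with few signals score high on
few peaks, and nominal mass cannot distinguish isobaric elemental
compositions. When accurate-mass spectra are available, two extra layers of
evidence become possible, and this package implements both, plus the
comparative machinery to quantify what the extra resolution buys:

1. **High-resolution filtering.** Every intense or high-m/z fragment is
   decomposed into candidate elemental formulas within a ppm tolerance
   (3 ppm by default), under ring-and-double-bond-equivalent (RDBE) limits,
   the SENIOR condition and element-ratio plausibility ranges. A proposed
   annotation with (derivatized) sum formula *F* is **confirmed** only when
   every checked fragment admits a composition that is an elementwise
   subformula of *F*; a single inexplicable fragment **falsifies** it.
2. **CI molecular-ion assignment.** Methane chemical ionization produces the
   adduct series [M−CH3]+, [M+H]+, [M+C2H5]+, [M+C3H5]+ with fixed spacings
   (CH4, C2H4, C). Detecting the series pins down the neutral mass M, which
   is linked back to the EI compound via retention index and shared
   fragments, and decomposed into molecular-formula candidates.

Around this sit the supporting layers a comparative study needs: TMS/MeOX
derivatization arithmetic (+C3H8Si per trimethylsilyl group, +CH3N per
methoxime), Kovats retention indices on an alkane ladder, NIST-style MSP
spectra I/O, weighted-cosine (dot product) library matching with
plausibility curation, QC-anchored signal drift correction, QC-RSD /
media-blank / missing-value filters, log-autoscale transforms, volcano
statistics (Welch t-tests, Benjamini–Hochberg FDR, fold-change > 2 and
adjusted p < 0.05 conventions), PCA, and a two-platform biomarker-overlap
report. A ground-truthed synthetic generator renders one compound set
through an accurate-mass channel and a unit-mass "twin" with an 8-fold
detection-limit handicap, so every claim about what high resolution adds is
testable against known truth.

Everything is tidyverse-shaped: functions take data frames (tibbles with
nested peak lists) first and return tibbles; fitted results have
`tidy()` / `glance()` / `autoplot()` methods.

## Worked example

```r
library(hrgcms)

monoisotopic_mass("C3H9Si", charge = 1)   # trimethylsilylium
#> [1] 73.0468

format_formula(derivatize("C6H12O6", n_tms = 5, n_meox = 1))
#> [1] "C22H55NO6Si5"   # glucose methoxime pentakis-TMS

cand <- decompose_mass(347.1139, decomposition_constraints(tolerance_ppm = 3))
head(cand[, 1:4], 3)
#> # A tibble: 3 x 4
#>   formula       theoretical_mass error_ppm  rdbe
#>   <chr>                    <dbl>     <dbl> <dbl>
#> 1 C13H26NO4PSi2             347.    -0.294     4
#> 2 C14H26NO3PSSi             347.     0.367     4
#> 3 C16H23N3P2Si              347.    -0.728     9

run <- full_run(twin_config(), seed = 1)
run
#> Twin-platform synthetic study (seed 1)
#> # A tibble: 12 x 2
#>    metric                     value
#>    <chr>                      <dbl>
#>  1 n_compounds_truth             60
#>  2 hr_detected                   60
#>  3 unit_detected                 42
#>  4 hr_post_filter                55
#>  5 unit_post_filter              38
#>  6 hr_significant                12
#>  7 unit_significant               7
#>  8 overlap_percent               58
#>  9 library_top1_accuracy_hr       1
#> 10 library_top1_accuracy_unit     1
#> 11 hr_filter_confirm_rate         1
#> 12 ci_mass_recovery_rate          1
```

Reading the summary: of 60 simulated compounds the accurate-mass channel
detects all 60 while the handicapped unit-mass channel deconvolves only 42;
after drift correction and QC/blank/missing filters 55 vs 38 remain; the
volcano analysis declares 12 vs 7 compounds significantly dysregulated, and
only 58% of the union is shared between platforms — the two instruments
agree on the multivariate picture but not on individual biomarkers. Library
matching is perfect on both channels, every true annotation survives
high-resolution filtering, and every CI adduct series yields the correct
neutral mass.

`autoplot(run$channels$hr$volcano)` and `autoplot(run$channels$hr$pca)`
draw the volcano and PCA score plots;
`tidy(run$channels$hr$volcano)` returns the per-compound table.

## Layout

- `R/` — formula arithmetic and decomposition (`decompose_mass`),
  spectra + MSP I/O, library matching, high-resolution filtering
  (`hr_filter_verdict`), CI adduct series (`detect_adduct_series`),
  feature-table filters and statistics (`volcano`, `pca_features`),
  platform comparison (`platform_overlap`), synthetic generator
  (`generate_compounds`, `generate_experiment`, `generate_decoys`), and
  the `full_run()` orchestrator.
- `vignettes/twin-platform-annotation.Rmd` — the methods vignette: model
  assumptions, parameter choices, generator design and limitations.
- `tests/testthat/` — unit, property and acceptance suites.
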