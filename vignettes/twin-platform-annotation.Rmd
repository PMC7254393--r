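---
title: "Methods: accurate-mass GC-MS annotation and the twin-platform design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: accurate-mass GC-MS annotation and the twin-platform design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrgcms)
```

This vignette documents the models, conventions and design choices behind
`hrgcms`: how the package verifies (or falsifies) GC-MS metabolite
annotations with accurate-mass data, how the quantitative filtering and
statistics are defined down to their boundary conventions, and what the
synthetic twin-platform generator does and does not emulate.

## The annotation problem

Derivatized-extract GC-MS identifies metabolites in three escalating steps.

**Step 1 — library matching.** Deconvoluted EI pseudospectra are compared
with unit-mass library spectra by a weighted-cosine ("dot product") match
factor. Libraries carry nominal-mass spectra, so the query is degraded to
unit mass first. A high score is necessary but not sufficient: a spectrum
with very few signals can reach a high cosine on a handful of shared bins.
`curate_hits()` therefore codifies three vetoes — minimum score (default
700), minimum matched bins (5) and minimum query peaks (20; spectra with
fewer fragments are trace-level and cannot be matched reliably).

**Step 2 — high-resolution filtering.** With accurate masses, each fragment
can be decomposed into elemental compositions within a ppm window. If the
annotation is correct, every fragment composition must be an elementwise
subformula of the proposed compound's derivatized sum formula (EI
rearrangements shuffle atoms internally; they cannot add atoms the molecule
does not have). `hr_filter_verdict()` checks the union of the 5 most
intense and 3 highest-m/z fragments: one inexplicable fragment falsifies
the proposal; confirmation requires at least 3 checked fragments, all
explained; fewer checkable fragments leave the verdict inconclusive.
Unit-mass spectra are rejected outright — at nominal mass every fragment is
"explainable" and the test carries no information, which is precisely the
verification gap of unit-mass instruments.

**Step 3 — CI molecular ions.** EI molecular ions are weak or absent, so
neutral masses come from methane chemical ionization. The adduct series
[M−CH3]+, [M+H]+, [M+C2H5]+ and [M+C3H5]+ has fixed spacings (CH4, C2H4,
C); `detect_adduct_series()` hypothesizes every peak as every member,
requires a configurable minimum of 3 of the 4 members within tolerance
(all four are not always observed — the default balances sensitivity
against chance alignments, and is a config knob), merges near-duplicate
mass hypotheses using the same ppm tolerance as detection (one knob, fewer
surprises), and refines M as the mean over matched members.
`link_ci_to_ei()` ties a CI hit to an EI compound by retention-index
agreement (default window 5 RI units) plus at least 2 shared fragment m/z
values; "similar sum formulas at the retention index" is operationalized as
shared-fragment matching because it is the observable proxy available at
the spectrum level.

## Chemistry conventions

* **Alphabet and masses.** All arithmetic runs over {C, H, N, O, P, S, Si}.
  Isotope masses and abundances ship as a plain-text table
  (`inst/extdata/isotopes.tsv`) so results are bit-stable and auditable.
* **Electron mass.** Ion masses are charge-aware: a cation m/z is the
  composition mass minus one electron mass (0.00055 Da). At 3 ppm and
  m/z < 200 the electron mass approaches the tolerance width, so ignoring
  it would bias fragment annotation.
* **Valence model.** One valence per element (C 4, Si 4, N 3, P 3, O 2,
  S 2, H 1). Multivalent states (S(VI), P(V)) are not enumerated —
  simplicity over completeness; the RDBE of e.g. sulfate esters is
  accordingly conventional, not structural.
* **RDBE and SENIOR.** RDBE = 1 + Σ n(v−2)/2; half-integer values flag
  ion/radical compositions and are admitted only for fragment-ion
  decomposition. The SENIOR condition (even valence sum, sum ≥ 2(atoms−1))
  applies to neutral molecular candidates only.
* **Element-ratio ranges.** The decomposition's plausibility screen uses
  the 99.7%-coverage ratio ranges (H/C in [0.2, 3.1]; N/C ≤ 1.3; O/C ≤ 1.2;
  P/C ≤ 0.3; S/C ≤ 0.8), with silicon counted as carbon because TMS groups
  extend the skeleton the way carbons do. Fragment annotation deliberately
  disables this screen: losses such as CO, or retained silyl cations, are
  legitimate fragment compositions with "impossible" molecular ratios. The
  subformula cap is the operative fragment filter.
* **Derivatization.** TMS adds C3H8Si (active H replaced by Si(CH3)3);
  MeOX adds CH3N (carbonyl O retained in the methoxime). Because only
  formulas are known, the oxygen count is the proxy precondition for
  methoximation; requesting more MeOX groups than oxygens is an error.
* **Kovats indices.** Temperature-programmed linear interpolation on a
  C7-C40 alkane ladder, no extrapolation outside the ladder span.

## Decomposition algorithm and determinism

`decompose_mass()` enumerates non-hydrogen element counts on a pruned grid
(every count capped by what fits under the window's upper edge) and solves
the hydrogen count analytically from the residual mass — exact, exhaustive,
and far smaller than the full lattice. Lattices above 1e8 points are
rejected with a size estimate. Output ordering is deterministic: absolute
ppm error, then lower RDBE, then lexicographic element counts. The tests
hold the implementation to an independent brute-force enumerator over the
full lattice (hydrogen included) with separately written filter
arithmetic.

## Spectral scoring

The match factor is the cosine of weighted vectors
`mz^a * intensity^b` over the union of integer bins, scaled to 0-999. The
exact weighting inside the commercial NIST search is not published, so the
default is the widely used square-root-intensity cosine (a = 0, b = 0.5),
with a NIST-like preset (a = 3, b = 0.6) one keyword away; the default
keeps all reported numbers reproducible from open code. The score is
symmetric and invariant under uniform intensity scaling; 999 is attained
exactly for proportional spectra.

## Quantitative pipeline conventions

* **Drift correction** divides each compound by a trend interpolated
  linearly between consecutive pooled-QC injections over injection order
  (flat beyond the first/last QC) and rescales to the compound's QC median.
  This deterministic, dependency-free scheme replaces tree-ensemble QC
  correctors deliberately: drift correction is treated as a preprocessing
  step whose output must be exactly reproducible in tests. A drift-free
  table is returned unchanged; fewer than 3 QCs is an error.
* **Filter boundaries.** QC-RSD "exceeding 20%" is strict (exactly 20%
  kept). The blank rule keeps a blank-detected compound only when its best
  experimental group mean is at least 5-fold the blank mean (boundary
  kept). The missing-value filter requires presence in ≥ 80% of at least
  one experimental group — the threshold itself is a package choice since
  only the existence of such a filter is given. Every filter returns
  disjoint kept/removed splits whose union is its input.
* **Transform.** Missing/non-positive areas are imputed as half the
  compound's minimum positive area (imputation applies to the transform
  and tests only; presence/absence filters operate on raw data), natural
  log, then per-compound autoscaling over experimental samples.
  Zero-variance compounds become zero rows with a warning, not an error.
* **Volcano.** Fold change is the raw-scale stress/control mean ratio
  (zero control mean gives an infinite fold change, still classifiable);
  p-values are two-sided Welch t-tests on log areas (no test variant is
  canonical for metabolomics tables; Welch is robust to unequal
  variances); adjustment is Benjamini-Hochberg (the conventional FDR
  flavor; a raw-p mode exists in config). Dysregulation is two-sided:
  FC > 2 or FC < 1/2, strict, with adjusted p < 0.05.
* **PCA** runs on the autoscaled matrix without further centering; each
  component's sign is fixed so its largest-magnitude loading is positive,
  making score plots reproducible.
* **Overlap.** The two-platform overlap percentage uses the union
  denominator, 100·shared/(shared + uniqueA + uniqueB), rounded to the
  nearest integer; with 21 shared and 9 + 46 unique significant compounds
  this evaluates to 28%. Each one-platform biomarker gets a cause code:
  below-LOD, blank-excluded, threshold-fail, or unmatched.

## The synthetic twin generator

`generate_compounds()` seeds formulas from ~60 curated primary metabolites
(amino acids, sugars, organic and fatty acids, polyols, algal osmolytes),
derivatizes them (TMS 1-6 bounded by heteroatom count, MeOX 0-1 when
oxygen permits), and builds EI fragments by subtracting random neutral-loss
combinations (CH3, H2O, CO, TMSOH, ...) from the derivatized formula —
every fragment is a subformula of its parent by construction, compositions
beyond hydrogen saturation (RDBE < −0.5) are discarded, and ion m/z is
confined to the 50-600 EI scan range. Molecular ions are emitted weakly or
omitted with probability 0.5, encoding the tendency of trap-based
instruments to lose low-abundance molecular ions. Retention indices are
collision-free on 800-3600; mean abundances are log-uniform over four
decades.

`generate_experiment()` renders a two-group design (defaults: 6 control,
6 stress, 5 pooled QCs evenly interleaved, 3 blanks — sizes chosen as a
typical small culture-flask experiment) with planted fold changes
(default: 25% of compounds, magnitude 2-8, direction random), log-normal
area noise (CV 10%, a routine QC-level figure), multiplicative linear
injection-order drift (15% across the run), and mass error of 0.5 ppm
(1 sigma), the accuracy class of a well-calibrated Orbitrap. The unit-mass
twin rounds m/z half-away-from-zero (how nominal libraries index peaks)
and raises the detection limit 8-fold — the sensitivity gap between the
platforms — so weak fragments drop out and trace compounds vanish; a
compound needs 3 observable fragments to be "deconvolvable" in a channel.
The CI channel carries the full adduct series (members below the 80 m/z
CI scan floor dropped) plus the three strongest EI fragments at low
intensity.

What the generator does **not** emulate: chromatographic peak shapes and
deconvolution artifacts (split/merged peaks, co-elution contamination),
correlated compound abundances, matrix effects, retention-time drift, or
realistic EI intensity distributions (intensities are generator
conventions; no test depends on their shape beyond relative-abundance
cutoffs). Passing the suite therefore demonstrates correctness of the
algorithms under the stated statistical structure, not instrument-level
realism — in particular, real deconvolution failures are one of the main
drivers of cross-platform disagreement and are represented here only
through the detection-limit mechanism.

`generate_decoys()` produces, per compound, the true derivatized formula
plus a decoy with the same nominal but different exact mass
(O <-> NH2, CH2 <-> N, Si <-> C2H4 swaps, all > 5 ppm apart), the
construction behind the decoy-discrimination guarantee: at 3 ppm the
high-resolution filter confirms essentially all true proposals while
falsifying ≥ 90% of decoys — the property that makes library hits
disprovable by accurate mass at all.

## Problem sizes and numerical tolerances

The test and acceptance suites run at desk scale: 100 random lattices
(≤ 1e6 points) for oracle equivalence, all ~60 curated formulas for
round-trip recovery at 1 ppm, 50 compounds for decoy discrimination,
100 molecules for CI recovery, 200-compound null and planted simulations
at n = 5/5, and a 60-compound twin study. These sizes give stable
pass/fail behavior at fixed seeds while keeping a full run in well under a
minute of compute per suite. Mass comparisons use relative (ppm)
tolerances throughout; equality checks on filters and orderings are exact.

## Known limitations

* Formula-level chemistry only: no structure generation, no in-silico
  bond-breaking fragmentation, no isomer discrimination (glucose and
  fructose share a formula; only retention separates them).
* One valence per element; no adducts beyond the four methane-CI members
  (ammonia adducts, for instance, are out of scope).
* The MeOX precondition uses oxygen count as a carbonyl proxy, so alcohols
  can be "methoximated" in simulation — harmless for mass arithmetic,
  wrong as chemistry.
* The element set searched per query defaults to the full alphabet; a
  practitioner would restrict it per compound using isotope-pattern
  evidence (`isotope_pattern()` provides the forward computation).
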