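---
title: "Methods: quantifying neutrophils, NETs and vessels in brain tissue cores"
author: "neutroquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying neutrophils, NETs and vessels in brain tissue cores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neutroquant)
```

## Overview

`neutroquant` quantifies multi-channel immunofluorescence of brain
tissue-microarray (TMA) cores: neutrophil and NET abundance, vessel
size-stratified lectin intensity (a glycocalyx readout), the vascular vs
parenchymal partition of myeloperoxidase (MPO) load, and the association
of extravascular MPO with amyloid plaques and pTau tangles. A synthetic
core generator with exact ground truth makes each stage testable without
access to human tissue. This vignette documents the model, every
parameter that matters, the numerical conventions, and the limits of
what the synthetic validation shows.

## The quantification model

**Preprocessing.** Each marker channel is background-corrected by
rolling-ball subtraction — the channel minus its grayscale opening with a
flat disc of radius 25 µm (well above the cell scale of 4–6 µm, well
below the vessel scale) — and, on the cell route, smoothed with a
Gaussian of sigma 1 µm. The vessel route is thresholded directly after
background subtraction: smoothing would grow a halo around crisp vessel
walls at the permissive threshold and bias the width measurement.

**Thresholding.** Three rules. *intense* selects bright, strongly
stained structures via an automatic between-class-variance (Otsu) split;
*all_vessel* is the same split scaled by a permissive factor 0.5 so mid-
and low-intensity vessels are kept; *fixed* applies a literal value. Two
safeguards make the automatic rules behave on TMA images. First, the
split is searched **within the tissue footprint** (0.5 × Otsu on the
heavily smoothed sum of channels): otherwise the dominant core-vs-glass
contrast hijacks the bimodal split and "intense" selects the entire
core. Second, when the chosen split would call more than 25% of tissue
pixels foreground — the degenerate outcome when bright structures are
extremely sparse (a control core may contain a single neutrophil) — the
rule falls back to a robust background ceiling, median + 5 MAD of the
in-tissue intensities. Every mask records the rule, the realised
threshold and which base produced it.

**Objects.** Connected components are labelled under 8-connectivity
(4 available) by a compiled two-pass union–find. Per object the package
measures area (µm²), centroid, bounding box, and the *moment width*
axes: with second central moments λ₁ ≥ λ₂ of the pixel coordinates, the
minor/major axis lengths are √(12(λ + 1/12)) µm. This uniform-profile
convention measures a tube's lumen width exactly — a d-pixel-wide
rasterised tube reports d — which is what a vessel-diameter cutoff means
physically. It differs from the equivalent-ellipse convention
(4√λ) by the factor √(4/3) ≈ 1.155 on rectangles; we chose the width
convention because the package's own validation demands that a 10 µm
tube not be classified as a >12 µm vessel, which the ellipse convention
cannot deliver. For elliptical objects the two conventions differ by
≈13%; cutoffs here are calibrated to the width convention.

**Cells.** Neutrophils are objects of the intense-MPO mask (size window
20–200 µm²; "large objects excluded") that *touch* an intense-S100A8
object. NETs are neutrophils that additionally touch an intense-CitH3
object, so every NET is MPO⁺S100A8⁺CitH3⁺ by construction. MPO objects
with no S100A8 contact are retained as diffuse MPO deposits, keeping the
MPO-only / S100A8-only / co-labelled overlap report complete.
"Touching" means footprints overlap or are pixel-adjacent
(8-connectivity); the tolerated gap is configurable (default 0), and a
strict pixel-overlap alternative is available
(`positivityRule = "overlap"`).

**Vessels and compartments.** Lectin vessels use the all-vessel
threshold, collagen IV vessels the intense threshold; both are filtered
to 20–50 000 µm². Vessels are classified small/large by minor axis
against 12 µm (lectin) or 15 µm (collagen IV); an exact tie goes to
"large" by default (configurable), with 10⁻⁹ slack so a tie computed
through `sqrt()` is not pushed to the wrong side by floating point. The
per-class lectin intensity is the unweighted mean of per-vessel means —
vessel-weighted, not pixel-pooled, so a single large vessel cannot
dominate its class. The intensity is measured on a background-corrected
channel whose ball background is estimated on a lightly smoothed copy
(sigma 2 µm): the opening of raw shot noise is dominated by near-zero
noise minima, which would make the correction a no-op, and the remaining
additive background would compress between-group intensity ratios. The
vessel mask (union of footprints dilated by 2 µm) defines compartments:
a cell or MPO pixel is vascular iff it intersects the mask. Load is
partitioned per pixel, so the vascular and extravascular shares always
sum exactly to the total; with zero total load the shares are reported
absent, never 0/0.

**Statistics.** Two-group comparisons use the two-tailed pooled-variance
Student's t-test (Welch by flag), with a Shapiro–Wilk normality check
reported but never used to switch tests automatically. Two-factor
designs use two-way ANOVA — classical sums of squares when balanced,
Type II via `car::Anova` otherwise — with Tukey HSD post-hoc on a
configurable margin. Correlations are Pearson, two-sided. The outlier
screen flags values more than 2 SD from their group mean, computing mean
and SD in a single pass with the candidate included; flagging is
reporting only — removal is a separate explicit step, mirroring a
workflow in which flagged cores are inspected for staining artefacts
before exclusion. No multiple-testing correction is applied across the
battery beyond Tukey within each ANOVA.

## The synthetic generator

`generateScene()` rasterises a circular tissue core (zero-signal
exterior, so tissue area and densities are well defined) containing:

- **vessels**: constant-diameter tubes along near-straight polylines
  (midpoint deflection ≤ 3% of length). In cohorts, chords are drawn as
  near-parallel lanes (one base angle per scene, evenly spread offsets)
  so tubes rarely cross and remain individually measurable; diameters
  are bimodal (uniform on 5–9.5 and 14.5–24 µm), deliberately clear of
  the 12 µm cutoff band. The lectin amplitude is 100 × the vessel's
  intensity factor (glycocalyx stand-in, (0, 1]); collagen IV is
  rendered for all vessels.
- **cells**: Gaussian-profiled discs (sigma = radius/2). Neutrophils
  (radius 4–6 µm) have MPO = S100A8 = 100; NETs are larger and dimmer
  (radius 6–8 µm, amplitude 70) and additionally CitH3⁺; diffuse MPO
  deposits and microglial MPO are dimmer still. With background 10 the
  peak signal-to-background is ≈10.
- **pathology**: plaques (radius 15 µm, amyloid-β channel) and tangles
  (radius 8 µm, pTau), optionally with a co-located diffuse MPO deposit
  so deposit–pathology touching holds by construction.
- **noise**: per channel, `Poisson(scale·x)/scale + N(0, sd)` clamped at
  zero, defaults scale 1, sd 2, background 10 inside the core. One seed
  drives all randomness; a scene is a pure function of its spec.

`generateCohort()` draws per-scene neutrophil counts as Poisson with
mean density × core area, assigns vascular placement and NET identity by
the group's vascular fraction and NET prevalence, and applies the
group's lectin factor and pathology densities. Default effect sizes
emulate a disease contrast: density 15 vs 45 cells/mm² (3×), NET
prevalence 0.1 vs 0.3, vascular fraction 0.8 in both groups, lectin
factor 1 vs 0.6, plaques and tangles only in the disease group.
Parenchymal cells keep a 10 µm clearance from vessel walls so
ground-truth compartments remain unambiguous under the 2 µm mask
dilation. `render = "truth"` skips channel rasterisation and returns the
identical ground-truth tables, which is how the statistical-calibration
studies generate hundreds of cohorts cheaply.

**What the generator does not emulate** — and hence what passing tests
do not show about real tissue: realistic polymorphic nuclear morphology,
vessel branching and strong tortuosity, staining gradients and
illumination fields, antibody cross-reactivity, section thickness
effects, or multiplexed round-to-round registration artefacts. Synthetic
validation demonstrates that the measurement chain is correct and
calibrated, not that the biology of any particular cohort is
reproduced.

## Numerical choices and edge cases

- Disc structuring elements use pixel-centre coverage
  (`sqrt(x² + y²) ≤ r + 0.5`), so a radius-3 disc has 37 pixels.
- Grayscale morphology runs through EBImage in a [0, 1] rescaled frame
  (EBImage clips outside that range); results are rescaled back exactly.
- A constant channel under an automatic threshold yields an empty mask
  with a warning (no bimodality to exploit).
- Border-touching objects are retained by default (TMA cores are small;
  exclusion would bias densities) and flagged per object.
- Degenerate statistics fail loudly or are flagged: both groups constant
  at different values is an error (reported, not silently skipped, in
  `cohortReport()`); a constant ANOVA response is flagged rather than
  reported as F = 0; zero-variance correlations are rejected.
- Identical runs are bit-identical: all randomness flows from explicit
  seeds, restored after use.

## Validation performed by the test suite

Property and acceptance tests (all seeds fixed) check: equality of
rolling-ball subtraction with a brute-force opening oracle, of the
touching rule with an all-pairs distance scan, of the load partition
with per-pixel counting, and of the ANOVA with a longhand
sums-of-squares decomposition (100 random instances each); exact
conservation of compartment counts and load shares; ≥95% precision and
recall for neutrophil detection at ≤50 cells/mm² and default noise; 100%
vessel size classification for diameters ≥2 µm from the cutoff; lectin
intensity factor recovery within 10%; type-I error of the two-group test
inside the binomial 95% band around 0.05 and ≥90% power for a 3× density
effect at n = 10 per group (100 replicates each, ground-truth render).
Study sizes were chosen to make each check statistically meaningful at
desk scale: 20 cores of 600² px for the co-labelling fidelity study,
400² px scenes for detection recovery, 200² px ground-truth cohorts for
calibration.

## Known limitations

- The minor axis of a strongly curved or branching vessel overestimates
  lumen width; synthetic validation uses near-straight tubes and the
  cohort generator limits curvature accordingly.
- Otsu-based rules assume background-dominated channels; fields whose
  signal covers more than roughly half the tissue would trip the robust
  fallback and should use a fixed threshold instead.
- Two true cells closer than the smoothing-plus-threshold footprint
  merge into one object; at the validated densities this affects a few
  percent of objects and is counted as recovered (not missed) by the
  recovery criterion's nearest-centroid definition.
- The per-class intensity summary is vessel-weighted by design; a
  pixel-pooled summary would weight classes differently and is not
  provided.
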