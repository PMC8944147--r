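# neutroquant

Quantification of neutrophils, neutrophil extracellular traps (NETs) and
blood vessels in multi-channel immunofluorescence of brain tissue
microarray (TMA) cores — and a synthetic-core generator with exact ground
truth so that every stage of the analysis can be validated end to end.

## The scientific problem

Neutrophils accumulate in the Alzheimer's disease (AD) brain, mostly
inside blood vessels, where the granule enzyme myeloperoxidase (MPO) they
carry can damage the vessel wall and the endothelial glycocalyx. Testing
such hypotheses on human TMA cohorts requires an auditable image
pipeline that can

- detect neutrophils as objects with **intense MPO and S100A8
  co-staining** (after rolling-ball background subtraction and
  smoothing, with large objects excluded),
- call **NETs** as objects triple-positive for CitH3, S100A8 and MPO,
- segment **vessels** from a UEA1-lectin channel with a permissive
  "all-vessel" threshold (or collagen IV with a high threshold), classify
  them as *small* or *large* by the minor axis length of the object
  (cutoffs 12 µm for lectin, 15 µm for collagen IV), and read out mean
  lectin intensity per size class as a glycocalyx proxy,
- partition **MPO load** into vascular vs extravascular compartments
  using the dilated vessel mask, and associate extravascular MPO with
  amyloid plaques and pTau tangles by the *object-touching* rule,
- aggregate per-core readouts into cohort statistics: two-tailed
  Student's t-tests for two groups, two-way ANOVA with Tukey's post-hoc
  for two factors, Pearson correlations, and an outlier screen flagging
  values > 2 SD outside the group mean.

Because the original tissue images cannot be redistributed, the package
ships a first-class synthetic generator (`generateScene()`,
`generateCohort()`) that emulates TMA cores — tubular vessels with a
tunable lectin intensity factor, Gaussian-profiled cells co-positive in
the configured channels, plaques/tangles with optional diffuse MPO
deposits, and a Poisson–Gaussian noise model — with exact ground-truth
tables for every object.

## Core conventions

For an object with second central moments λ₁ ≥ λ₂ of its pixel
coordinates, the reported axis lengths are the *moment widths*
√(12(λ + 1/12)) µm, which measure a tube's true lumen width exactly
(a d-pixel-wide rectangle measures d). Thresholds are automatic
(between-class-variance/Otsu searched within the tissue footprint, with a
robust background guard), scaled by the rule's multiplier, and every mask
records its realised threshold in its provenance. "Touching" means
footprints overlapping or pixel-adjacent under 8-connectivity (gap
configurable). Compartment and load partitions are exact: vascular +
extravascular = total on every input.

## Worked example

```r
library(neutroquant)

cs  <- cohortSpec(nPerGroup = 3, seed = 42, imageShape = c(300L, 300L),
                  density = c(40, 120))          # cells per mm^2 per group
cfg <- runConfig(mode = "synthetic", cohort = cs, outDir = "nq_demo")
res <- runPipeline(cfg)

res$cores[, c("core_id", "group", "n_neutrophils", "neutrophil_density_mm2",
              "vascular_fraction", "mean_lectin_small")]
#>    core_id   group n_neutrophils neutrophil_density_mm2 vascular_fraction mean_lectin_small
#> 1 core_001 control             4                   65.4             0.750             101.2
#> 2 core_002 control             2                   33.7             1.000             101.0
#> 3 core_003 control             2                   35.0             1.000             101.1
#> 4 core_004      AD             5                   83.8             1.000              60.6
#> 5 core_005      AD             5                   81.5             0.600              60.1
#> 6 core_006      AD             6                   97.6             0.667              61.1

res$stats$tidy[, c("measure", "statistic", "df", "p_value")]
#>                  measure statistic df  p_value
#> 1 neutrophil_density_mm2     3.736  4 2.02e-02
#> 2                 n_nets     1.512  4 2.05e-01
#> 3      vascular_fraction    -1.080  4 3.41e-01
#> 4     mpo_vascular_share    -0.633  4 5.61e-01
#> 5      mean_lectin_small  -136.402  4 1.73e-08
#> 6      mean_lectin_large   -15.973  4 8.98e-05
```

Reading the output: the generator was asked for a 3× neutrophil density
effect and a lectin intensity factor of 0.6 in the AD group. The pipeline
recovers a significant density difference (t-test, p = 0.02), strongly
reduced lectin intensity in both vessel size classes (the per-class means
sit near 100 × factor after background correction), a vascular majority of
neutrophils in both groups, and — with only three cores per group — no
significant difference in the vascular fraction, as expected under equal
group settings for that parameter. `nq_demo/` additionally contains
`cores.csv`, `cells.csv`, `vessels.csv`, `stats.csv` and a
`manifest.json` with the config fingerprint and every realised threshold.

A thin command-line front end with `simulate` / `quantify` / `run` verbs
is included at `inst/scripts/neutroquant-cli.R`.

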