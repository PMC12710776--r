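# ffaquant

Automated quantification of fundus fluorescein angiography (FFA) frame
series, across species.

## The problem

FFA traces an intravenous fluorescein bolus through the retinal
circulation. With an intact inner blood–retina barrier the dye stays in the
vessels and clears within minutes; where the barrier leaks, extravascular
dye accumulates and the late-phase signal settles onto an elevated plateau.
Subtle leakage differences — for example between a morning and an evening
session of the same eye — are invisible to inspection and tedious to
quantify by hand: each session is a series of ~20 frames that must be
decoded, time-stamped, motion-corrected, segmented and averaged before a
single number exists.

`ffaquant` is a batch pipeline for exactly that workflow, aimed at
researchers quantifying retinal vascular integrity in mice, non-human
primates and humans. It provides:

* **Ingestion** — TIFF/PNG/JPEG/BMP/DICOM decoding to a uniform `[0, 1]`
  intensity model; acquisition-time recovery from metadata, filename
  patterns, sidecar tables or burned-in timestamps (template-matching OCR
  against a packaged digit atlas); per-study manifests.
* **Registration** — FAST keypoints with rotated binary descriptors and
  seeded RANSAC (primates) or sub-pixel phase correlation (rodents), with
  automatic exclusion of frames that fail quality gates, and a maximum
  intensity projection (MIP) per series.
* **Segmentation** — circular field-of-view detection, the standard
  1/3/6 mm ETDRS macular grid (fovea / parafovea / perifovea / extrafovea)
  around a supplied macula centre, and multi-scale Hessian ridge masking of
  large vessels. Mice are quantified over the whole field of view minus
  major vessels (the microvasculature).
* **Temporal metrics** — intensity-versus-time tables, cumulative intensity
  over cohort-common timepoints, early/intermediate/late angiographic phase
  summaries, percent-of-max decay profiles, per-subject AM-versus-PM percent
  change, and ETDRS leakage colour maps.
* **Statistics** — an Anderson–Darling normality gate on paired differences
  dispatching to a paired *t* test or an exact Wilcoxon matched-pairs
  signed-rank test; nested-eye mixed-effects models (`lme4`/`lmerTest`)
  with Šidák-adjusted comparisons; machine-readable CSV/JSON reports.
* **A synthetic FFA simulator** — branching vessel trees, gamma-variate dye
  kinetics with a programmable circadian leakage contrast, motion,
  vignetting, noise and timestamps — with exact ground truth, so every
  stage of the pipeline is validated against known answers.

The core readout is the per-subject percent change of a leakage metric
between sessions, `Δ% = 100·(PM − AM)/AM`, summarised over the cohort and
tested with the normality-gated engine.

## A worked example

Simulate a 4-subject mouse study with a 30% evening leakage contrast,
process it, and analyse the late phase:

```r
library(ffaquant)

study_dir <- file.path(tempdir(), "demo_study")
cfg_sim <- synthetic_study_config(n_subjects = 4, delta = 0.3, seed = 7)
truth <- generate_study(cfg_sim, study_dir)
truth$analytic$late_pct_change
#> [1] 19.26713

cfg <- study_config(species = "mouse")
processed <- process_study(study_dir, cfg)
analysis  <- analyze_study(processed, cfg)
analysis$pct_summary
#> # A tibble: 1 × 4
#>   region     n mean_pct_change median_pct_change
#>   <chr>  <int>           <dbl>             <dbl>
#> 1 fov        4            19.8              19.8

tidy(analysis$comparisons)[, c("region", "n", "mean_pct_change", "test", "p")]
#> # A tibble: 1 × 5
#>   region     n mean_pct_change test                     p
#>   <chr>  <int>           <dbl> <chr>                <dbl>
#> 1 fov        4            19.8 wilcoxon_signed_rank 0.125
```

The generator programmed a leakage plateau 30% higher in the evening; only
part of the late-phase signal is leakage (the rest is residual intravascular
dye), so the analytic expectation is a ~19% late-phase increase — and the
pipeline recovers it from the rendered, jittered, noisy frames. At n = 4 the
exact Wilcoxon test cannot reach significance (its smallest two-tailed p is
0.125); the full validation cohorts use n = 15, where the same contrast is
detected at p < 1e-4. With `delta = 0` the estimate centres on 0% and the
test does not reject.

Plots: `plot_intensity_curves(analysis$records)` draws the cohort
morning/evening intensity-versus-time traces;
`autoplot(analysis)` shows the per-subject AM/PM pairing;
`leakage_color_map()` renders the regional Δ% onto the ETDRS rings.

A thin command-line wrapper (`inst/cli/ffaquant`) exposes the same stages as
`simulate`, `process` and `analyze` subcommands for shell pipelines.

## Package notes

The methods vignette (`vignettes/ffaquant-methods.Rmd`) documents the
models, the default parameters and why they were chosen, what the synthetic
generator does and does not emulate, and the package's known limitations.
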