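---
title: "Quantifying retinal vascular leakage from FFA series: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying retinal vascular leakage from FFA series: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffaquant)
```

## The measurement problem

Fundus fluorescein angiography (FFA) traces an intravenous fluorescein bolus
through the retinal circulation. In a healthy inner blood–retina barrier the
dye stays intravascular and clears within minutes; where the barrier is
compromised, dye extravasates and the extravascular signal settles onto a
plateau that outlasts the bolus. The readout of interest is therefore not a
single image but the *temporal profile* of regional intensity over a roughly
ten-minute session, and in circadian designs the contrast between a morning
(AM) and an evening (PM) session of the same eye.

`ffaquant` turns directories of per-session frame series into that readout:
it decodes heterogeneous image files, recovers per-frame acquisition times,
registers each series to a common reference, restricts statistics to the
imaged field of view (FOV), masks large vessels, extracts regional
intensity-versus-time tables, and feeds them to a normality-gated statistical
engine. A synthetic angiography generator with known ground truth makes each
stage testable without clinical data.

## Pipeline model and assumptions

**Intensity domain.** All pixels are mapped to `[0, 1]` by the container's
bit depth at decode time. Everything downstream — registration quality
gates, ridge responses, intensity records — operates on this scale, so TIFF,
PNG, JPEG, BMP and DICOM inputs are commensurable. The assumption is that
acquisition gain is held constant *within* a study arm, which is how FFA
sessions are normally captured; the pipeline makes no attempt to calibrate
across instruments.

**Time recovery.** Seconds post-injection per frame come from the first
successful source in a configured order (default: embedded metadata, then a
filename pattern, then a sidecar `filename,seconds` table, then burned-in
timestamp OCR). The OCR stage is deliberately not a general text engine: it
is normalized cross-correlation against a packaged 5×7 digit atlas, with a
0.7 correlation floor per glyph and an explicit ambiguity error when two
glyphs score within 0.02 of each other. That keeps the stage dependency-free
and exactly testable: the synthetic generator stamps overlays from the same
atlas.

**Registration.** Within a session the eye drifts and blinks; frames must be
aligned before any pixelwise statistic. Two strategies are dispatched by
species:

* *Keypoint (primates):* FAST corners (segment test on the radius-3 Bresenham
  circle, arc length 9, score = the largest threshold at which the corner
  survives, 3×3 non-maximum suppression with the supporting arc length as
  tie-break, at most 15,000 kept per image), intensity-centroid orientations,
  256-bit rotated binary descriptors sampled from a frozen pattern, Hamming
  matching with a 0.8 best/second-best ratio, and a seeded 2,000-iteration
  RANSAC similarity fit (2 px inlier tolerance) refined by least squares.
* *Frequency (rodents):* raised-cosine windowing, phase correlation, and
  local matrix-DFT upsampling to sub-pixel translation. Rodent frames carry
  too few stable corners for descriptors, while their motion is almost purely
  translational, which is exactly the regime phase correlation handles best.

The reference frame is the one with the highest mean intensity inside the
FOV — the early bright phase, where structure is strongest. Frames are
excluded, with reason codes, when they yield fewer than 50 keypoints, fewer
than 10 RANSAC inliers, a mean inlier residual above 3 px, or a
phase-correlation peak ratio below 1.5 (the ratio of the main peak to the
second-highest non-adjacent peak). These gate values are package choices:
they sit far from both failure modes on synthetic data (clean frames
register with residuals around 0.1 px and peak ratios above 5; blurred or
near-dark frames fall below every gate). A series aborts when more than half
its frames are excluded.

**Field of view.** All statistics are restricted to the imaged circular
aperture. The FOV is detected *after* registration, on the maximum intensity
projection (MIP), because a mask detected on unregistered frames is blurred
by the jitter and admits dark rim pixels. Detection thresholds a heavily
smoothed copy (washing out vasculature-scale structure), refines the
boundary on a lighter smoothing, and then replaces the component by a disk:
the centre comes from a low-threshold component that hugs the aperture in
every sector, the radius from the steepest descent of the azimuthally
averaged radial profile, searched near the component radius. The
circularization step matters quantitatively: an intensity isophote bulges
outward where vessels reach the rim and inward in dark sectors, which
selectively enriches vessel pixels in the analysis region and biases the
AM/PM contrast. On a synthetic disk of known radius the detected area is
accurate to well under 1%.

**Illumination correction is for registration only.** The white top-hat
(frame minus its morphological opening with a disk of radius
`ceiling(min(h, w) / 8)`, which exceeds the widest vessel) removes shadows
and slow gradients that destabilise feature detection. But diffuse leakage
*is* a slow spatial signal — the top-hat would subtract the very quantity
under study — so intensities are always extracted from the registered
uncorrected frames, and the corrected copies feed feature detection alone.
A config switch (`illumination`) exposes this.

**Vessel masking.** Large vessels carry intravascular dye whose kinetics
differ from parenchymal leakage, so they are excluded before averaging: a
multi-scale Hessian bright-ridge response (scale-normalised, evaluated only
at configured large-vessel scales), thresholded at a quantile of the in-FOV
response, dilated by 2 px. For mice the complement within the FOV *is* the
microvasculature analysis region; for primates the mask is subtracted from
the ETDRS regions (exposed as a per-species switch, defaulting to
exclusion, since published pipelines are ambiguous on this point). The
fraction masked is capped at half the FOV.

**ETDRS grid.** The macular grid uses the standard 1, 3, 6 mm ring diameters
around a user-supplied macula centre (the centre is an explicit input — no
automatic fovea detection), converted to pixels via the acquisition pixel
scale; when that scale is unavailable the fallback radii are (0.055, 0.165,
0.33) of the image width, flagged in reports. Region membership is decided
by pixel centre, so fovea + parafovea + perifovea equals the 6 mm disk
exactly and the rasterized ring areas sit within 2% of their analytic
values. Quadrant subdivision is omitted; the analyses are ring-level.

## Temporal metrics

Acquisition times jitter around the nominal schedule (default 30 s to
600 s in 30 s steps, the conventional rodent protocol), so records are first
snapped to the nearest scheduled time when within 25% of the schedule step;
collisions keep the nearer frame and off-schedule records are flagged, not
silently dropped. On the binned records the package computes:

* **Phase summaries** over the conventional angiographic windows — early
  `[0, 60)` s, intermediate `[120, 240]` s, late `(240, end]` s. The
  60–120 s gap is deliberately unassigned, as the conventional phase
  definitions imply.
* **Cumulative intensity** summed over the timepoints present in *every*
  series of the cohort, so subjects with missed frames do not bias the sum.
* **Decay profiles** as percent of the profile maximum, with the peak time
  and the first time the profile falls to the clearance threshold (default
  50%, a package choice exposed in config).
* **AM-versus-PM percent change** per subject, `100 * (PM - AM) / AM`, with
  the cohort summarised by the mean of per-subject changes (the median is
  reported alongside, since intensity data are typically non-normal).
* **Leakage colour maps**: ETDRS rings filled white-to-dark-red in
  proportion to the regional percent change, zero or negative change left
  uncoloured, with a numeric legend rendered from the digit atlas. Output is
  deterministic to the byte for fixed input.

## The statistical engine

Each paired comparison is gated by an Anderson–Darling normality test *on
the paired differences* — the quantity whose distribution the paired tests
assume. The statistic uses the case-3 form (mean and variance estimated)
with the small-sample adjustment `A*² = A²(1 + 0.75/n + 2.25/n²)`; the
verdict at α = 0.05 uses the standard critical value 0.752, and the reported
band (`<0.0005`, `<0.005`, `<0.05`, `≥0.05`) mirrors how such results are
conventionally printed. A normal verdict dispatches to the paired t test
(delegated to `stats::t.test`), otherwise to the Wilcoxon matched-pairs
signed-rank test, implemented here with mid-ranks, zero differences dropped
(the classic convention, stated in reports), and an *exact* two-tailed p for
up to 25 effective pairs, computed from the full distribution of the
positive-rank sum over all sign assignments; beyond that a normal
approximation with tie and continuity corrections takes over. The exact
path agrees with a brute-force enumeration oracle to machine precision, and
with `stats::wilcox.test` whenever ties are absent. Families of comparisons
(the ETDRS regions of one metric) receive Šidák-adjusted p values,
`1 - (1 - p)^m`.

With fewer than 8 pairs the normality test is undefined and the
nonparametric branch is taken, noted in the result row. Data are never
transformed toward normality; the engine switches tests instead.

When both eyes of a subject enter the analysis, observations are nested and
a mixed model replaces the paired tests: `value ~ session + (1 | subject)`
(plus `* group` and Šidák-adjusted pairwise session contrasts in the
two-way form), fitted by REML through `lmerTest` with Satterthwaite degrees
of freedom. A singular fit — zero between-subject variance — falls back to
the fixed-effects analogue with a logged note.

On simulated data the engine calibrates as it should: the Anderson–Darling
gate rejects ~5% of Gaussian samples at n = 200 and essentially every
exponential sample; the gated paired comparison holds its 5% size over a
thousand null cohorts; and the nested-eye model recovers a programmed
session effect of 0.1 (subject SD 0.05, noise SD 0.02, six subjects × two
eyes) with estimates concentrated well inside ±0.03.

## The synthetic angiography generator

The generator is the package's oracle, and its defaults are the study
conditions every validation runs under: 15 subjects, one eye, AM and PM
sessions, 256×256 frames, the 30–600 s schedule. Those sizes keep a full
simulate–process–analyze cycle to a few minutes on one core while leaving
every stage's failure modes reachable; they are stated here as the package's
validation conditions, and all tests and the acceptance script use them.

Each subject receives a random bifurcating vessel tree grown from the
optic-disc margin: six roots, five generations, child widths following
Murray's law (`w · 2^(-1/3)`), trunk full width 8 px — about 3% of the image
width, matching major retinal vessels of roughly 100 µm in a ~3 mm field.
Ground truth records every centreline segment and width; segments of full
width ≥ 5 px (the first three generations) define the "major vessels" that
masking should remove.

Dye kinetics are a gamma-variate bolus normalised to peak amplitude
`K = 0.55` at `t0 + αβ = 30` s (`t0 = 5` s, `α = 2.5`, `β = 10` s), a
diffuse leakage term `L (1 - e^{-s/τ})` with `τ = 120` s — so the plateau
emerges by about four minutes — and an intravascular plateau
`V_p (1 - e^{-s/τ})` on the vessels themselves (`V_p = 0.12`), reflecting
recirculating dye: real late-phase angiograms still show vasculature, and
without this term late frames would be featureless and unregistrable. The
circadian contrast enters *only* through the leakage amplitude:
`L_PM = (1 + δ) L_AM`, with `L_AM = 0.12`.

A frame at time `t` is the textured background plus the uniform leakage term
plus the tree scaled by the vascular terms, multiplied by a radial vignette
(strength 0.3), warped by a per-frame random motion (translations up to
±8 px; rotations only for primate configurations), degraded by additive
(SD 0.005) and signal-proportional (SD 0.01) Gaussian noise — levels
appropriate to hardware frame-averaging, which FFA instruments apply at
acquisition — and cropped to a dark surround outside the aperture disk at
94% of the half-width. Scene and noise use separate seeded RNG streams, so
anatomy can be held fixed while noise varies. Identical configurations
reproduce byte-identical studies.

Because only `L` differs between sessions, the late-phase percent change has
a closed form per subject: `100 · δ ·` (leakage share of the late AM
signal), with the share computed exactly from the subject's rendered anatomy
over the analysis region (FOV minus major trunks). The ground-truth JSON
carries these analytic values; end-to-end validation checks that the
pipeline's cohort estimate brackets them (bootstrap 95% interval over
subjects) at `δ = 0.3` and stays within ±3 percentage points of zero at
`δ = 0`.

**What the generator does not emulate** — and hence what passing tests do
not certify about clinical data: pathology (haemorrhage, neovascular
fronds, edema), choroidal layering and its early-phase dominance,
instrument-specific nonlinearities and gain drift, saccadic distortion
within a frame, and cross-session anatomical change. The generator's AM and
PM sessions share anatomy exactly; real paired sessions differ by
positioning, which the paper-level design absorbs into the paired
statistics rather than the image pipeline.

## Numerical choices and degenerate inputs

* Area-averaged downscaling uses exact interval-overlap weights, so a
  constant image survives any resize unchanged and the pixel scale metadata
  is rescaled with the frame.
* Bilinear resampling marks out-of-canvas pixels invalid (`NA`); they are
  excluded from every mean, and the MIP treats a pixel invalid in all
  frames as 0 (flagged in its coverage attribute).
* FAST breaks score ties by the longer supporting arc, then by row-major
  position, making detection order-free; the descriptor sampling pattern is
  generated once from a frozen seed, so descriptors are machine-independent.
* RANSAC is seeded from config: identical inputs and seed give identical
  transforms.
* Degenerate inputs raise typed conditions rather than propagating NaNs:
  constant samples (Anderson–Darling), all-zero difference vectors
  (Wilcoxon), all-dark frames (FOV detection, phase correlation), empty
  schedules, over-cropping, clipped ETDRS grids, non-positive AM baselines.
* Zero differences are dropped before ranking; mid-ranks double to integers
  internally so the exact Wilcoxon distribution is computed without
  floating-point rank arithmetic.

## Known limitations

Cross-session (AM-to-PM) registration is deliberately absent — each session
is aligned only internally, so the AM and PM analysis regions coincide only
up to FOV detection; the disk-fit FOV keeps this mismatch small but not
zero. Non-rigid distortion is not modelled; the similarity/translation
family suffices for the motion the generator emulates and for typical
cooperative-subject FFA, not for large saccades. The vessel mask is a
ridge-quantile heuristic: it removes major trunks well and spares
microvasculature by design, but its masked fraction tracks the configured
quantile, not the true vessel load, so extreme anatomies warrant the config
override. DICOM support covers uncompressed little-endian monochrome
objects — the subset FFA exports use — not the full standard.
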