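---
title: "Quantifying vaginal microvasculature and epithelial thickness from endoscopic OCT/OCTA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying vaginal microvasculature and epithelial thickness from endoscopic OCT/OCTA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octavet)
```

## The measurement problem

Genitourinary syndrome of menopause (GSM) thins the vaginal epithelium and
rarefies the microvasculature of the lamina propria. Energy-based
treatments (e.g. fractional CO~2~ laser) aim to reverse both, but the
standard instruments for judging success — the clinician-scored Vaginal
Health Index (VHI, five items scored 1–5, total 5–25) and the
patient-reported Vulvovaginal Symptom Questionnaire (VSQ, higher = worse) —
are subjective. Endoscopic optical coherence tomography (OCT) resolves the
wall's layered anatomy at ~14 µm axial scale, and OCT angiography (OCTA)
adds motion contrast: repeated B-scans at the same position decorrelate
where blood flows and stay identical where tissue is static.

This package turns those two image contrasts into two objective
biomarkers:

* **BVD** (blood vessel density) — the fraction of en-face area with
  detected flow, and
* **VET** (vaginal epithelial thickness) — the depth of the dark band
  between the bright surface reflection and the bright lamina propria,

plus the longitudinal statistics used to follow them over a treatment
course. Because no patient imaging is distributable, the package also
contains a synthetic-data module that generates physically plausible
phantoms and cohorts with known ground truth; every algorithmic claim in
the test suite is a recovery experiment against that truth.

## Flow contrast: intensity-based Doppler variance

With J + 1 repeated frames, the amplitude `A[j, z]` at one A-line feeds
the Doppler-variance statistic

$$\sigma^2 \;=\; 1 - \frac{\sum_{j=1}^{J} A_{j,z}\,A_{j+1,z}}
{\sum_{j=1}^{J} \tfrac{1}{2}\!\left(A_{j,z}^2 + A_{j+1,z}^2\right)}.$$

Two properties anchor the implementation and are asserted exactly in the
tests:

* **Static limit.** Identical frames give numerator = denominator, hence
  $\sigma^2 = 0$ voxel by voxel. By the AM–GM inequality the statistic is
  confined to [0, 1] for any non-negative amplitudes.
* **Rayleigh asymptote.** For fully developed speckle the amplitude is
  Rayleigh distributed; when frames are independent,
  $\mathbb{E}[A_j A_{j+1}] = \mathbb{E}[A]^2$ and
  $\mathbb{E}[A^2]$ normalise to $\mathbb{E}[\sigma^2] \to 1 - \pi/4
  \approx 0.2146$. The suite checks this on 1.5×10^4^ voxels at J = 64
  against a Monte-Carlo standard error; the small-sample bias of the ratio
  estimator at J = 64 is ~5×10⁻⁵, negligible against that band.

Design choices the data did not dictate:

* **Pairing.** The index j can run over neighbouring A-lines within one
  frame (µs time scale) or over repeated frames at the same A-line (ms
  time scale). The inter-frame form is the default — the longer interval
  gives far higher flow sensitivity — and intra-frame pairing is kept as
  an option (`pairing = "intraframe"`).
* **Lateral window.** The "number of averaged A-lines" is realised as
  pairs × window: sums run over the J frame pairs and over a lateral
  window of 3 A-lines (configurable) centred on the output column. This
  denoises without changing the statistic's fixed points.
* **Zero denominator.** Voxels with no signal at all (air above the
  probe) are defined as $\sigma^2 = 0$ so the background stays dark; a
  zero denominator implies a zero numerator, so no information is lost.
* **Repeats.** Four frames per position (J = 3 in routine use) is an
  engineering default; the repeat count is a `phantom_geometry` field and
  every function accepts any J ≥ 1.

En-face angiograms are the depth average of $\sigma^2$ over an inclusive
slab (`enface_project`). The slab is a configuration choice; for phantoms
the generator records the depth band its vessels occupy, which the
analysis scripts use directly.

## Vessel enhancement and density

The en-face angiogram is enhanced with the standard multi-scale Hessian
(Frangi) vesselness: at each Gaussian scale the Hessian eigenvalues
$|\lambda_1| \le |\lambda_2|$ yield blobness $R_b = \lambda_1/\lambda_2$
and structure strength $S = \sqrt{\lambda_1^2 + \lambda_2^2}$, combined as
$\exp(-R_b^2/2\beta^2)\,\big(1 - \exp(-S^2/2c^2)\big)$, zeroed where
$\lambda_2 \ge 0$ (flow is bright, so a vessel is a bright ridge), and
maximised over scales.

Parameter defaults: scales 1–4 px (matching tube radii of 1–4 en-face
pixels at ~35 µm/px), β = 0.5 (the conventional blobness sensitivity),
and c set per scale to half the maximum Hessian norm — the usual
auto-scaling, so the filter is contrast-invariant. A constant image has a
zero Hessian and returns an identically zero map (guarded explicitly,
since FFT round-off would otherwise be amplified by the normalisation).

Binarization defaults to Otsu's threshold on the vesselness map
(threshold-free and reproducible; a fixed threshold is available for
regression tests), with two refinements chosen on tube phantoms during
algorithm design:

* **Hysteresis** (Canny-style): pixels above half the Otsu threshold are
  kept when connected to an above-threshold seed. The Frangi response of
  thin or deep tubes fades along their length; a single cut either drops
  those continuations or floods the background, while the connectivity
  condition keeps the former and rejects the latter. Without it the
  recovered area is biased low by ~0.05–0.08 at dense networks; with it
  the bias is within ±0.04 across densities and seeds.
* A **5×5 morphological closing** refills the response dips at vessel
  junctions, where the local geometry is not tubular.

With both, the full chain (speckle rendering → IBDV → en-face → Frangi →
binarization) recovers generating en-face vessel fractions of
0.10/0.20/0.30 within ±0.05, which the acceptance suite asserts.

BVD is then a pure counting ratio: vessel pixels within the region of
interest divided by region pixels.

## Epithelium segmentation and VET

In a structural B-scan the epithelium is the dark band between two bright
features: the specular surface reflection and the backscattering lamina
propria. Both of its boundaries are therefore dark-to-bright transitions
along depth, which the classical segmenter exploits:

1. smooth (Gaussian, σ = 1 px axial, 2 px lateral), normalise by the 99th
   percentile;
2. estimate the surface per column as the first strong crossing, and
   reject the image if there is no dark air region above a bright
   interface ("surface not found");
3. refine the surface with a dynamic-programming shortest path through
   the axial-gradient cost image, with a smoothness penalty proportional
   to the vertical jump between neighbouring columns (0.1 × `jump_cost`
   per pixel, `jump_cost = 2`) — single-column speckle outliers cannot
   pull the boundary;
4. track the lower boundary the same way inside a thickness gate of
   3–60 px below the surface (about 40–840 µm at 14 µm/px, generous
   around the 100–200 µm range of atrophic to healthy epithelium);
5. decide per column whether a dark band actually separates the two
   boundaries. The darkness statistics use a laterally-only smoothed
   image: axial smoothing would bleed the bright surface line and lamina
   into a thin band and destroy the contrast this test needs. If there is
   no dark band and the tissue right below the surface is bright, the
   column has zero thickness (boundaries coincide — a legal outcome, not
   an error); if everything below is dark and featureless the column is
   marked invalid and excluded from the mean.

VET is the per-column boundary separation times the axial pixel size,
averaged over valid columns; the validity fraction is reported alongside.
Thickness is measured along z only — no refraction or incidence-angle
correction is applied.

On speckle phantoms the recovered scan means deviate from generating
truths of 100/150/200 µm by 7.0/3.7/0.7 µm (all within one 14-µm pixel)
with per-column boundary MAD well under 2 px; the residual error at
100 µm comes from a handful of columns where a 7-px band is locally
obscured by speckle.

### The encoder–decoder alternative

A second segmenter is a small 3-level encoder–decoder convolutional
network with skip connections (channels 8/16/32, 3×3 kernels, ~1.2×10⁵
weights), trained with binary cross-entropy + soft-Dice loss under Adam.
It is implemented in plain R via im2col matrix multiplication: at 64×64
inputs a framework adds nothing, and training is exactly reproducible
under a seed. Inference resizes an arbitrary B-scan to the network grid,
predicts per-pixel epithelium probability, thresholds at 0.6 (the
deployed operating point), keeps the largest connected band, and extracts
per-column boundaries.

Trained on 200 synthetic pairs for ~10 epochs (seconds of CPU time) it
reaches validation Dice ≈ 0.98 at the 0.6 threshold, and agrees with the
classical segmenter within one axial pixel of mean VET on clean phantoms.
The classical path remains the default: it needs no training artefact and
is bit-reproducible.

Segmentation quality is scored by pixel accuracy, IoU and Dice; two empty
masks score 1 on all three by convention (the identity
dice = 2·iou/(1 + iou) is property-tested).

## The synthetic study

### Speckle model

Every voxel carries a complex circular-Gaussian field whose variance is
the local mean reflectivity, so amplitudes are Rayleigh (fully developed
speckle) with the characteristic mean/SD ratio
$\sqrt{\pi/(4-\pi)} \approx 1.913$, which the tests verify in uniform
blocks. Static tissue keeps one speckle realisation across repeats;
vessel voxels evolve between consecutive frames as
$E_{j+1} = \sqrt{1-d}\,E_j + \sqrt{d}\,E^{\text{new}}$, the simplest
model with an analytic inter-frame correlation (1 − d). Independent
complex detection noise of mean-square amplitude `noise_floor`² is added
per frame. Mean IBDV inside vessels is strictly increasing in d, checked
at d ∈ {0, 0.25, 0.5, 1}.

### Anatomy

Scenes are layered: dark air, a 2-px bright specular surface line on a
gently undulating interface, a dark epithelium band of configurable
thickness (rounded to the 14 µm depth grid), bright lamina propria, and
3-D vessel tubes — random-walk centerlines with round cross-sections of
radius 1–4 en-face pixels, confined to a recorded depth band below the
deepest epithelium. Tubes are appended (the last one stopping mid-stroke)
until the en-face area fraction is within 0.02 of target. An optional
grid pattern of enhanced surface reflectivity emulates a fractional-laser
treatment footprint. Default grid: 256×256×64 at 14 µm axial / ~35 µm
lateral (a 9 mm field) with 4 repeats; tests and scripts use 128×128×24
for desk-scale runtime.

### Cohort model

The cohort generator draws one record per (patient, visit 1–4, location ∈
{da, dp, pa, pp}) around deterministic cell means: grand means
interpolate linearly from baseline to final visit (defaults: BVD
21.7% → 29.6%, VET 123.3 → 160.3 µm), with per-location offsets making
the proximal-anterior site respond most (BVD 22.6% → 31.3%, VET
+46.6 µm). Around the means sit a patient-level random effect (shared
across that patient's 16 records) and a record-level residual, both
4-variate normal over (BVD, VET, VHI, VSQ).

The configured score–metric correlations (defaults |r| = 0.754 VHI–VSQ,
0.310 VSQ–BVD, 0.384 VHI–BVD, 0.853 VHI–VET, 0.721 VSQ–VET; VSQ oriented
negatively since higher = worse) are *pooled-record* targets. Pooled
covariance decomposes into the deterministic visit/location trend plus
the random part; the generator computes the trend covariance from the
cell means analytically and solves for the random correlation matrix that
makes the pooled value hit the target, projecting to the nearest valid
correlation matrix if needed. The BVD–VET correlation (0.40) and the
VHI/VSQ means and SDs are design choices on the scales' plausible ranges.
VHI totals are rounded to integers and clamped to 5–25, VSQ to 0–21; the
resulting attenuation is below 0.01 in |r|. At n = 400 the realised
magnitudes land within ±0.02 of target and classify identically to the
configured values.

### What the phantoms do not emulate

No attenuation or light-propagation physics, no probe-motion or contact
artefacts, no bulk-motion phase noise, no hemodynamics (vessels are
geometric tubes with a single decorrelation parameter), no real epithelial
texture or pathology. Passing recovery tests therefore demonstrates that
the algorithms invert the stated generative model at realistic SNR — not
clinical-grade performance on patient images, which would require the
(unavailable) clinical data.

## Longitudinal statistics

* `aggregate_study`: arithmetic cell means with SEs and counts per
  (visit, location), plus grand per-visit means pooling the locations.
  Absent cells are reported absent, never imputed.
* `compare_to_baseline`: two-sided paired t-test (default) or Wilcoxon
  signed-rank on per-patient deltas of visit v against visit 1 (or the
  previous visit with `comparison = "consecutive"`); patients missing
  either visit are excluded pairwise, fewer than 3 pairs is an error.
  All-equal deltas are resolved analytically (p = 1 when all are zero).
  Stars follow the usual convention: ``***`` p < 0.001, ``**`` p < 0.01,
  ``*`` p < 0.05, else ns. Type-I error is calibrated: on 1000 null
  cohorts the rejection rate at α = 0.05 stays inside the binomial 95%
  band. No multiplicity correction is applied by default (use
  `p.adjust` on the returned p-values if desired).
* `correlate_metrics` / `classify_correlation`: Pearson r on pooled
  records (grouping optional), classified by |r| with left-closed bands —
  < 0.1 negligible, [0.1, 0.3) weak, [0.3, 0.5) moderate, ≥ 0.5 strong.
  The boundary convention is closed on the left so that 0.310 is moderate
  and 0.5 is strong, matching how coefficients at the band edges are
  conventionally reported.

## Numerical conventions and degenerate inputs

* Depth (z) increases downward from the frame top; indices are 1-based;
  depth slabs are inclusive ranges.
* The epithelium mask is true exactly on rows `upper ≤ z < lower`, so
  thickness = lower − upper pixels and a zero-thickness column has an
  empty mask.
* σ² is clamped to [0, 1] against float round-off; the vectorized
  evaluation matches a literal per-voxel transcription of the formula to
  10⁻¹².
* Volumes are written as multi-page 32-bit float TIFF scaled into [0, 1]
  with the scale factor (and geometry, seeds, page order) in a JSON
  sidecar; round trips are lossless to ~10⁻⁷ relative. Cohorts are plain
  CSV with a fixed schema.
* All generators and the network trainer are bit-reproducible under their
  seed arguments.

## Problem sizes

The test and acceptance runs use: 128×128×24 phantoms (4 repeats) for the
angiography chain; 128×128×8 for segmentation; J = 64 with 1.5×10⁴ voxels
for the Rayleigh asymptote; 200 patients for cohort recovery; 1000
replicates of 10-patient null cohorts for type-I calibration; and
200/50-pair training/validation sets at 64×64 for the network. These
sizes were chosen so the whole suite runs on a laptop-class single core
in minutes while keeping Monte-Carlo bands tight enough to be
informative.
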