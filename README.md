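# octavet

Quantitative analysis of vaginal health from endoscopic OCT/OCTA:
microvasculature and epithelial thickness as objective biomarkers of
treatment response in genitourinary syndrome of menopause (GSM).

Energy-based GSM treatments are currently judged with subjective scores —
the clinician's Vaginal Health Index (VHI) and the patient-reported
Vulvovaginal Symptom Questionnaire (VSQ). Endoscopic optical coherence
tomography (OCT) and OCT angiography (OCTA) can measure what those scores
only infer: how thick the epithelium is and how dense the microvasculature
beneath it. This package implements the full computational chain, and a
synthetic phantom/cohort generator that provides ground truth for every
stage, so the whole pipeline is verifiable without patient data.

## What it computes

**Flow contrast.** From J + 1 repeated B-scans, the intensity-based
Doppler variance (IBDV)

σ² = 1 − Σⱼ AⱼAⱼ₊₁ / Σⱼ (Aⱼ² + Aⱼ₊₁²)/2,

which is exactly 0 for static tissue, confined to [0, 1] for any
amplitudes, and approaches the Rayleigh limit 1 − π/4 ≈ 0.2146 where
speckle fully decorrelates (flowing blood). Depth-averaging a slab gives
the en-face angiogram.

**Blood vessel density (BVD).** The angiogram is enhanced with a
multi-scale Hessian (Frangi) vesselness filter, binarized (Otsu + a small
closing that refills junction gaps), and BVD is the vessel-area fraction
of the measured region.

**Vaginal epithelial thickness (VET).** The epithelium appears as a dark
band between the bright surface reflection and the bright lamina propria.
A dynamic-programming boundary tracker finds both dark-to-bright
transitions per column (a small encoder–decoder network trained on
synthetic pairs is available as an alternative, deployed at a 0.6
probability threshold); VET is the boundary separation in µm.

**Longitudinal statistics.** Per-visit/per-location aggregation, paired
t-tests (or Wilcoxon) of each visit against baseline with the usual star
annotations (\*\*\* p < 0.001, \*\* p < 0.01, \* p < 0.05), and Pearson
correlations classified by |r|: < 0.1 negligible, 0.1–0.3 weak, 0.3–0.5
moderate, ≥ 0.5 strong.

**Synthetic data.** Rayleigh-speckle phantoms (layered vaginal wall,
3-D vessel tubes with tunable inter-frame decorrelation, optional
post-ablation grid pattern) and longitudinal cohorts whose effect sizes
default to the treatment-response magnitudes the method targets
(grand-mean BVD 21.7% → 29.6%, VET 123.3 → 160.3 µm over four visits,
with the proximal-anterior site responding most); score–metric
correlations are calibrated to configurable pooled targets.

## Worked example

The `analysis/` scripts run the whole study end to end
(`Rscript analysis/01_simulate.R` … `05_stats.R`), writing tables under
`results/study/`. The same chain in a session:

```r
library(octavet)

g  <- phantom_geometry(n_depth = 128, n_fast = 128, n_slow = 24)
sc <- make_tissue_scene(g, thickness_um = 150, vessel_fraction = 0.20,
                        seed = 1)
vol <- render_phantom_volume(sc, decorrelation = 1, noise_floor = 0.05,
                             seed = 2)

ef   <- enface_project(compute_ibdv_volume(vol, 3), sc$vessel_depth_band)
mask <- binarize_vessels(frangi_vesselness(ef))
compute_bvd(mask)
#> BVD = 21.1% (649 of 3072 pixels)        # generating truth: 20.2%

seg <- segment_epithelium_classical(vol$structural[, , 12])
compute_vet(seg, g$axial_pixel_um)
#> VET = 156.7 um (validity 100%)          # generating truth: 150 um (11 px)

tab <- generate_cohort(cohort_effect_model(n_patients = 25, seed = 3))
correlate_metrics(tab, "vhi", "vet_um")
#> Pearson r = 0.859 (|r| = 0.859, strong, n = 400)
compare_to_baseline(tab, "bvd")        # per-location deltas vs visit 1,
                                       # p-values and significance stars
```

The recovered BVD sits within the ±5-point band the pipeline is
specified to hold over vessel fractions 0.10–0.30, and the recovered VET
within one 14-µm axial pixel of truth; the cohort correlation lands at
its configured strength class.

## Layout

```
R/                  package code (simulation, IBDV, Frangi/BVD,
                    segmentation/VET, network, statistics, I/O)
analysis/           numbered stage scripts for the simulated study
scripts/acceptance.R  headline-quantity reproduction
tests/testthat/     unit, property and end-to-end recovery tests
vignettes/          methods vignette (models, parameters, design choices)
```
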