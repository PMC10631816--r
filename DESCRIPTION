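Package: octavet
Title: Quantitative OCT Angiography of Vaginal Tissue: Vessel Density and
    Epithelial Thickness
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for endoscopic optical coherence tomography
    (OCT) and OCT angiography (OCTA) assessment of vaginal health. Computes
    intensity-based Doppler variance (IBDV) flow contrast from repeated
    B-scans, en-face angiograms, multi-scale Frangi vesselness enhancement
    and blood vessel density (BVD), epithelium segmentation and vaginal
    epithelial thickness (VET) with both a classical boundary-tracking
    segmenter and a small encoder-decoder network, and longitudinal cohort
    statistics (baseline comparisons with significance stars, Pearson
    correlation strength classification). Includes a speckle-realistic
    synthetic phantom and cohort generator so every stage is verifiable
    against known ground truth without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    tiff,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
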