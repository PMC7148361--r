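Package: octaquant
Title: Quantification of Choroidal Neovascularisation in En-Face OCT Angiography Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of en-face optical coherence
    tomography angiography (OCTA) images of choroidal neovascularisation
    (CNV). Provides a synthetic speckled-vasculature phantom generator,
    frame registration and averaging, classical denoisers, lesion cropping,
    global and local Otsu binarisation, topology-preserving skeletonisation,
    the standard vessel metrics (vessel density, vessel length density,
    vessel diameter index with Littmann/Bennett magnification correction,
    box-counting fractal dimension, contrast-to-noise ratio), and a
    three-arm repeated-measures ANOVA comparison with Bonferroni pairwise
    tests, driven by a reproducible end-to-end study runner.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    png,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
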