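Package: pethet
Title: Intratumoral Heterogeneity Analysis of FDG-PET Volumes with Survival Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies intratumoral metabolic heterogeneity on FDG-PET
    volumes and relates it to progression-free survival. Provides standardized
    uptake value (SUV) conversion and NIfTI input/output, fixed-SUV isocontour
    tumor segmentation, 64-level gray-scale quantization, local and regional
    texture features from co-occurrence, neighborhood intensity difference,
    run-length and size-zone matrices, Spearman screening of texture panels
    against co-occurrence entropy, hazard-ratio-maximizing cutoff
    dichotomization, Cox proportional-hazards modelling and Harrell's
    concordance-index comparison, plus generators for textured lesion phantoms
    and survival cohorts with known hazard structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    survival,
    igraph,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
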