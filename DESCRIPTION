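Package: densefuse
Title: Multiscale Non-Local Patch-Based Multi-Atlas Brain Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Whole-brain MRI segmentation by multiscale non-local patch-based
    multi-atlas label fusion, accelerated with approximate nearest neighbor
    fields (PatchMatch-style), with a patch-based boosted ensemble corrector
    for systematic segmentation errors, partial-volume boundary curation
    operators, multiscale label grouping (structures, tissues, lobes), and
    volumetric and asymmetry reporting. Includes a labeled brain phantom
    generator producing deformed atlas libraries with optional white-matter
    lesions for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    RNifti,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
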