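Package: podoquant
Title: Automated Podometrics from Multiplexed Immunofluorescence Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies podocyte density and YAP nuclear localization in
    kidney biopsy sections from multi-channel immunofluorescence images.
    Segments glomerular tufts from GLEPP1 staining and nuclear profiles
    from Hoechst/DAPI, classifies podocytes by TLE4 intensity thresholds,
    and converts per-section profile counts into volumetric podocyte
    density using a slab-section stereological model (Abercrombie-type
    thickness correction and Weibel-Gomez tuft volume estimation).
    Includes nuclear/cytoplasmic YAP translocation scoring for cultured
    cells, grade-stratified cohort statistics, and a synthetic phantom
    generator with ground-truth manifests for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
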