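Package: petcontour
Title: Iso-Contour Transformation and Ordinal Malignancy Ranking of PET
    Lung Nodules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Pre-processing and analysis pipeline for FDG-PET imaging of
    solitary hypermetabolic pulmonary nodules. Reads PET DICOM series,
    computes standardised uptake values (SUV), transforms axial slices
    into nested iso-contour structures (resampling to 1 mm pixels,
    min-max normalisation, grayscale contour rendering), extracts four
    ordinal visual features (contour nesting degree, contour shape
    change, shift of the maximum-uptake locus, size of the contour
    enclosing the maximum), and ranks nodules by malignancy likelihood
    with a synthetic variable based on the generalised distance measure
    for ordinal data (GDM2) from a pattern object, segmented by the
    maximum-gradient method. Includes a synthetic PET phantom generator
    and a minimal PET DICOM reader/writer so the full pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
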