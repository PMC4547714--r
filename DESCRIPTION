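Package: canalcurve
Title: Lumbar Spinal Curvature Assessment from the Spinal Canal Centerline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated assessment of lumbar spinal curvature from 3-D CT-like
    volumes. Segments the spinal canal by coarse-to-fine morphological region
    growing and edge-guided surface refinement, extracts the canal centerline
    by fast-marching minimal paths, normalizes the lumbar segment between the
    T12 inferior and S1 superior endplate planes into a dimensionless common
    frame, computes six curve shape descriptors (segment length, curve length,
    curvedness, lordosis peak location and cranial/caudal peak heights),
    builds median population curve models, and compares two populations
    pointwise and per descriptor with two-sample t-tests. A seeded phantom
    generator supplies ground-truthed synthetic volumes and curve populations
    so every stage is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
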