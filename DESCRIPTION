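Package: acoustosort
Title: Digital Twin of an Image-Activated Acoustofluidic Cell Sorter
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale simulator of image-activated cell sorting with
    focused travelling surface acoustic waves (TSAW) downstream of real-time
    deformability cytometry (RT-DC). Generates ground-truth-annotated
    synthetic event tables, Poisson arrival streams and microscopy frame
    stacks; re-implements the real-time morphometric feature pipeline
    (background subtraction, sub-pixel contour detection, convex hull,
    deformation, area ratio, brightness); implements the acoustofluidic
    physics (standing- and travelling-wave radiation forces, acoustic
    contrast factor, kappa-factor regime classification, Stokes drag,
    quasi-steady lateral displacement); and simulates end-to-end sorting
    runs with coincidence modelling, reporting purity, enrichment, recovery
    and throughput. Tidyverse-native: event tables in and tibbles out, with
    ggplot2 plotting and broom-style tidiers for run reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
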