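Package: retlesion
Title: Image-Guided Retinal Laser Lesioning Pipeline for Multimodal OCT/SLO
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hardware-free computational pipeline for multimodal retinal imaging
    and navigated laser-lesion delivery in the murine eye: polynomial
    galvanometer voltage-to-position calibration with Newton inversion,
    OCT volume processing (repeat averaging, RPE/OPL surface detection,
    digital flattening, layer-bounded en face projection), SLO frame-stack
    quality control, registration and averaging, tdTomato red-to-green
    fluorescence photoconversion quantification, OCT/SLO grid-target
    co-registration by polynomial unwarp, focal and raster-patch lesion
    planning with spot-overlap geometry and exclusion masks, firing-schedule
    compilation, and automated OCT lesion segmentation with a compact 2D
    U-Net trained and evaluated by cross-validated Dice. A synthetic
    murine-retina phantom generates OCT volumes, two-channel SLO sequences,
    grid-calibration targets and exact ground truth, so every stage is
    testable without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    jsonlite,
    rlang,
    tiff,
    png,
    igraph,
    ggplot2,
    generics,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
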