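Package: arrayscreen
Title: Analysis of Arrayed CRISPR Viability and Imaging Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for arrayed CRISPR knockout screens read out
    by luminescence viability assays and fluorescence microscopy. Provides
    plate-map and readout handling, background subtraction and
    control-based viability normalization, likelihood-ratio LOD scoring of
    guide effects against normal models of positive and negative control
    wells with control quality checks, nuclear and Golgi image
    quantification (watershed nucleus segmentation, per-object intensity
    and area measurements, top-hat spot segmentation), a protein-turnover
    targetability classifier based on one- and two-state degradation
    models, and seeded synthetic-data generators that emit plates, screens,
    microscopy fields and turnover tables with ground truth for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
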