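Package: nemorph
Title: Morphometry of the Reforming Nuclear Envelope from Volume Electron
    Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative morphometry of the reforming nuclear envelope (NE)
    in volume electron microscopy data. Detects and sizes vesicles in 3D label
    volumes by a sphericity criterion, identifies NE discontinuities (gaps),
    classifies them by vertical area and computes vesicle densities in
    close/far vicinity fields around gap endpoints; measures in situ NE rim
    curvature at nuclear pores from tomographic volumes via clip extraction,
    envelope alignment, en-face rotation search and membrane-midline tracing,
    converting rim diameters to curvature by kappa = 2/RD. Includes a
    ground-truthed synthetic phantom generator (telophase-like scenes and
    nuclear-pore tomogram clips) so every measurement stage is verifiable by
    parameter recovery, plus the accompanying statistical battery
    (Shapiro-Wilk gating, Kruskal-Wallis with Dunn's post hoc, one-way ANOVA
    with Tukey's HSD, median +/- IQR/2 summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
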