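Package: orgatrack
Title: Label-Free Organoid Growth Analysis from Brightfield Time-Lapse Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies organoid growth in label-free brightfield time-lapse
    recordings. Tiled z-stacks are reduced to stitched average-intensity
    projections, projected luminal areas are segmented by marker-controlled
    morphological watershed, labeled regions are measured and linked into
    per-organoid trajectories, and growth is summarized as normalized
    projected area (NPA) curves with per-condition medians, relative-size
    tables and a nonparametric statistical layer (Shapiro-Wilk gating,
    two-sample t, Mann-Whitney, Kruskal-Wallis with Bonferroni post-hoc).
    Includes a seeded synthetic time-lapse generator with ground truth so
    the whole pipeline is testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    tiff,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
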