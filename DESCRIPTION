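Package: fragtrace
Title: Fragment-Length Profiling of Cell-Free DNA from Electrophoresis Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Transforms gel-electrophoresis images or electropherogram signal
    tables of cell-free DNA into size-calibrated, concentration-normalized
    fragment-length profiles. Detects size-standard (ladder) peaks, matches
    them to an annotation file and interpolates base-pair coordinates for
    every migration position; computes nucleosomal size fractions, sample
    peak sizes, genomic-DNA contamination flags and distribution descriptors
    (entropy, skewness, short-to-long ratio); stratifies samples by a
    metadata table and compares groups with rank-based tests; and renders
    density traces and heatmaps. Includes a fully seeded synthetic
    electropherogram and gel-image generator so the whole pipeline can be
    exercised without instrument data, plus a command-line entry point for
    batch screening of directories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    ggplot2,
    rlang,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
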