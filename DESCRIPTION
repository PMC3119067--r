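Package: cytopop
Title: Headless Flow Cytometry Analysis with Automated Population Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless toolkit for multicolor flow cytometry analysis:
    reading and writing FCS 3.0 list-mode files and CSV event tables, a
    hierarchical workspace of datasets and clusterings, per-channel monotone
    transforms (linear, log10, hyperlog), automated population discovery by
    deterministic over-seeded k-means with iterative shape-based cluster
    merging, optimal cross-run cluster matching for stable display colors,
    cluster isolation into child datasets, figure export to common vector and
    raster formats, two-file session persistence, a directory-based plugin
    system, and a command-line interface. A synthetic-data generator with
    known ground-truth labels supports testing and demonstration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
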