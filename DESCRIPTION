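Package: nicheweb
Title: Niche Breadth, Niche Overlap Networks and Stable Module Groups
    Along Degradation Gradients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quadrat-survey community analysis for space-for-time degradation
    gradients: species importance values from relative height, cover and
    frequency; Levins niche breadth and Levins/Pianka pairwise niche overlap
    from species-by-sampling-unit utilization matrices; overlap-interval
    spectra; weighted niche-overlap networks with modularity-maximizing module
    detection (greedy agglomerative with local refinement, deterministic
    multilevel, and an exhaustive small-graph oracle); and identification of
    species groups with stable module membership across stages. Includes a
    synthetic-community generator with known niche structure for end-to-end
    validation, and a packaged species-by-stage reference table.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
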