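Package: mirtfnet
Title: TF-miRNA Co-Regulatory Network Construction and Motif Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds combinatorial transcription-factor (TF) and microRNA
    (miRNA) co-regulatory networks from typed interaction tables and
    user-supplied deregulated gene/miRNA sets, extracts disease-specific
    subnetworks with coverage ratios, identifies key network players via
    four centrality measures and minimum dominating sets, detects and
    statistically validates four classes of TF-miRNA-gene feed-forward-loop
    motifs against degree-preserving randomized networks, and tests the
    functional homogeneity of co-regulated genes with a permutation null
    and one-sided Kolmogorov-Smirnov test.  Includes a synthetic-data
    generator with planted structure so every stage can be validated
    without external database content.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
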