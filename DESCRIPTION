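Package: homst
Title: High-Order Minimum Spanning Tree Functional Connectivity Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds dynamic (sliding-window) functional connectivity networks
    from regional brain time series, derives each subject's high-order network
    as the correlation among ROI-pair correlation time series, reduces it to
    its strongest-weight spanning tree via descending-order Kruskal, extracts
    local tree metrics (degree, eccentricity, betweenness) and discriminative
    frequent subgraphs (gSpan with minimum DFS codes), and classifies subjects
    with a normalized multikernel support vector machine combining a
    Weisfeiler-Lehman subtree graph kernel with a vector kernel on selected
    features. Includes a seeded synthetic-cohort generator with
    group-modulated dynamic coupling for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    kernlab,
    stats,
    tools,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
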