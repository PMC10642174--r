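Package: declogic
Title: Discrete Decisional-Logic Models of Bio-Behavioral Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing signed, directed bio-behavioral regulatory
    networks under a four-level discrete decisional logic in the tradition of
    Thomas-style logical models. Nodes take qualitative levels 0-3; each edge
    carries a perception threshold and a positive integer weight, and a node
    moves one level toward the sign of its perceived weighted input. The
    package reads and validates signed edge lists with literature-evidence
    counts, computes descriptive graph statistics (density, clustering,
    closeness, betweenness), simulates synchronous and asynchronous dynamics
    with attractor classification and predecessor search, fits per-edge logic
    parameters and hidden molecular states to partially observed
    neuropsychological profiles by constraint satisfaction, tests fixed-point
    persistence of observed symptom profiles, and derives group-level
    differential biomarker predictions with one-sample t-tests under
    Benjamini-Hochberg false discovery rate control. A synthetic-study
    generator produces reproducible network + planted-program +
    subject-snapshot bundles for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
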