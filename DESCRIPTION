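Package: interbrain
Title: Inter-Brain Coactivation Graphs and the Bootstrap Modularity Test
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Graph-theoretic analysis of two-subject ("hyperscanning")
    multichannel recordings, motivated by fNIRS teacher-child studies.
    Builds inter-brain Spearman correlation graphs between the channels of
    two simultaneously recorded subjects, screens dyads for coactivation
    with a permutation ("bootstrap") test on Newman-Girvan modularity, and
    ranks hub channels with degree centrality, cross-dyad node relevance
    and eigenvector centrality.  Includes an optional modified
    Beer-Lambert preprocessing stage for raw dual-wavelength intensity
    data, a calibrated synthetic dyad generator for validation, SVG graph
    rendering on 10-10 scalp layouts, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    signal,
    zoo,
    jsonlite,
    yaml,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
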