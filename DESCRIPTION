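Package: protosym
Title: Multilevel Evolution of Protocell Replicators and Strand Symmetry Breaking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual-based simulation of protocells containing populations of
    self-replicating template/catalyst molecules under conflicting multilevel
    selection. Implements the two-step replication reaction scheme (complex
    formation, replication with mutation, decay) with exact particle-count
    conservation, multinomial substrate diffusion, threshold-triggered binomial
    cell division, single-lineage assays against an infinite background
    population (division counting and bottleneck-induced growth restoration),
    a minimal hierarchical Moran model of functional symmetry breaking, and
    analysis utilities (strand asymmetry metrics, variance effective population
    size, mutational variance decomposition, phase classification and scans).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp (>= 1.0.0),
    stats,
    utils,
    jsonlite,
    yaml,
    digest
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
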