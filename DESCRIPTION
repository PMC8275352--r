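Package: bmf
Title: Bipartite Motif Discovery for RNA-Binding Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Thermodynamic modelling of RNA-binding proteins with two
    cooperatively binding domains. Learns, from enriched versus background
    sequence sets, a k-mer binding-energy table for each domain core and a
    negative-binomial distribution for the linker distance between them, by
    maximum-likelihood stochastic gradient ascent with analytic gradients
    propagated through the dynamic-programming partition function. Trained
    models score new sequences by their binding probability via
    sliding-window averaging, and can be summarised by Boltzmann k-mer
    probabilities, spacer-length statistics, core similarity, motif entropy
    and sequence repetitiveness. Includes a synthetic benchmark generator
    with implanted bipartite motifs and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    graphics,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
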