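Package: pfnet
Title: Centrality Analysis of Protein Sequence Feature Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts composition and arrangement features from protein
    sequences (natural-vector counts, mean positions and normalized second
    moments; averaged property factors; pseudo amino acid composition),
    estimates pairwise relations between feature series with absolute
    correlation, normalized mutual information rate and bias-corrected
    transfer entropy, builds weighted feature networks, and ranks features
    by normalized centralities over permutation ensembles using pairwise
    one-sided Welch t-tests. Includes a synthetic-data generator for
    class-structured sequences and feature series with planted linear,
    nonlinear and directed (autoregressive) dependence, and a reader for
    MAT-format PDB identifier lists.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    MASS,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    car,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
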