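Package: panhomology
Title: K-mer-Prefiltered Homology Group Inference Across Proteomes
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers homology groups (orthologs and paralogs) across many
    protein sets. Candidate protein pairs are prefiltered with a
    frequency-filtered hexamer inverted index, scored by Smith-Waterman
    local alignment with BLOSUM62 and affine gaps, normalized by the
    shorter protein's self-alignment score, assembled into a thresholded
    similarity graph, and each connected component is rescaled and split
    into homology groups by Markov clustering. Includes a best-overlap
    recall/precision/F-score evaluator and a seeded multi-species
    protein-family simulator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    Matrix,
    igraph,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
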