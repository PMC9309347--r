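Package: remodnet
Title: Network Proximity Analysis of Drug Targets in Post-Infarction Remodeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for asking whether a drug's targets sit
    close to a disease protein signature in a confidence-thresholded
    protein-protein interaction network. Builds a post-myocardial-infarction
    remodeling signature from two-group microarray differential expression
    (quantile normalization, empirical-Bayes moderated t, Benjamini-Hochberg
    adjustment), translates it across species by reciprocal best hits,
    assembles the signature-plus-drug-target interaction network with
    degree-based edge enrichment statistics, ranks proteins and drug target
    sets by shortest-distance proximity against a degree-matched permutation
    null, quantifies mechanism overlap between drug classes, and partitions
    the network into modules by spectral K-means with elbow selection of K.
    Ships a synthetic-data generator with planted ground truth for every
    pipeline input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    limma,
    fgsea,
    withr,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
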