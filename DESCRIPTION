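Package: photognn
Title: Genome Neighborhood Network Features for Photosynthetic Protein
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Extracts genome-neighborhood conservation features from
    prokaryotic genome collections and uses them to classify
    photosynthetic versus non-photosynthetic proteins.  Gene
    neighborhoods are called from strand and intergenic-distance rules,
    proteins are grouped into families by Markov clustering of a
    sequence-similarity network at several E-value stringencies, and the
    conservation of each (query family, neighbor family) adjacency is
    scored by the total branch length of a neighbor-joining tree over
    the genomes carrying it.  The resulting profiles are discretized,
    exported to ARFF, and fed to a random-forest (or SVM / naive Bayes)
    classifier with gain-ratio feature ranking, PCA, class balancing and
    nested cross-validation.  A synthetic-collection generator with
    planted conserved neighborhoods makes the whole pipeline testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    Matrix,
    randomForest,
    e1071,
    foreign,
    jsonlite,
    stats,
    utils,
    tools,
    methods,
    Biostrings,
    GenomicRanges,
    rtracklayer,
    S4Vectors,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
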