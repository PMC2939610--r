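Package: multiscreen
Title: Multidimensional Candidate-Gene Screening for Case-Control SNP Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A multidimensional screen for candidate disease genes from
    case-control SNP genotype counts. Scores each SNP with an exact
    Beta-function Bayes factor (uniform priors on per-genotype case
    probabilities), maps risk SNPs to genes within a 500 kb window and
    intersects them with disease loci, classifies the resulting test set
    against known disease genes with ensembles of RBF-kernel support vector
    machines trained on randomized negative sets (evaluated by n-fold
    cross-validated sensitivity, specificity and accuracy), and retains
    candidates annotated to at least one PIRSF family, GO term or KEGG
    pathway enriched among known disease genes. A Fisher exact test with
    Bonferroni correction provides the traditional GWAS baseline, and a
    synthetic-fixture generator provides seeded inputs with planted truth
    for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    withr,
    jsonlite,
    yaml,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    fgsea
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
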