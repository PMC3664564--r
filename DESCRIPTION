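Package: mirlink
Title: Integrated miRNA-mRNA Differential Expression and Target Pairing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An integrated two-platform transcriptomics workflow for small
    case-control studies: present-calling and rank-based differential
    expression with an exact Mann-Whitney test and a complete-separation
    ("distinctly expressed") criterion, canonical seed-match miRNA target
    prediction over 3'UTR sequences, assembly of candidate miRNA-mRNA pairs
    under an opposite-direction regulation rule, GO biological-process
    counting with hypergeometric enrichment, unsupervised structure checks
    (average-linkage clustering on correlation similarity, PCA on z-scored
    values), and qPCR standard-curve validation with a permutation-based
    Spearman concordance test. Includes a synthetic-data generator that
    plants differential expression, complete separation, seed sites and
    miRNA-target pairs with known ground truth, so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings,
    BiocGenerics,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
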