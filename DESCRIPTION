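Package: fdtx
Title: Multi-Tissue Transcriptome Dysregulation Analysis for a Familial Dysautonomia Mouse Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for studying tissue-specific transcriptome
    dysregulation driven by reduced full-length ELP1 in a humanized familial
    dysautonomia (FD) mouse model. Provides negative-binomial Wald differential
    expression with surrogate-variable covariates, signed co-expression module
    discovery with eigengenes and cross-tissue module preservation, ELP1
    dose-responsive gene screening, FD-signature protein-protein interaction
    network statistics (hubs, shortest distances from the driver), cross-tissue
    convergence statistics including rank-rank hypergeometric overlap maps,
    MCA-based single-cell neuronal-subtype marker signatures, Fisher gene-set
    enrichment with redundancy pruning, and seeded synthetic-data generators
    with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    fgsea,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    mclust,
    DESeq2,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
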