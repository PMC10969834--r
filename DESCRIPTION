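Package: circlex
Title: Circular-Reprogramming Omics Comparison of Isogenic Neural Stem Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for isogenic 'circular reprogramming' designs in
    which somatic stem cells are reprogrammed to pluripotency and re-differentiated
    into the original lineage, so that residual transcriptional and DNA-methylation
    differences can be attributed to reprogramming itself rather than somatic
    memory.  Provides seeded generators for synthetic expression and Illumina
    450K-style beta-value data with planted X-chromosomal effects; surrogate
    variable analysis by residual SVD with permutation-based parallel analysis;
    per-gene differential expression with Benjamini-Hochberg correction and
    fold-change filtering; hypergeometric chromosome, gene-set and imprinted-gene
    enrichment; delta-beta differential methylation calling; sliding-window
    positional enrichment scans and expression/methylation co-localization;
    non-negative matrix factorization based pluripotency and neurality scoring
    with non-negative logistic weights and NNLS projection; and correlation-based
    hierarchical clustering, subset PCA and silhouette separation summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    cluster,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
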