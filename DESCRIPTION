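Package: plsvip
Title: Partial Least Squares VIP Gene Selection with Permutation FDR,
    Enrichment and Network Hub Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Differential expression analysis for two-group (case/control)
    transcriptomic studies based on partial least squares (PLS) regression.
    Latent variables are extracted with the NIPALS algorithm, genes are
    scored by variable importance in projection (VIP) weighted by the
    squared Pearson correlation of each latent score with the phenotype,
    the number of latent variables is chosen by stratified k-fold
    cross-validation of prediction accuracy, and significance is assigned
    by a pooled label-permutation false discovery rate. Downstream stages
    provide hypergeometric gene-set enrichment with Benjamini-Hochberg
    adjustment and degree-based hub detection on a protein-protein
    interaction subnetwork. A synthetic-data module generates expression
    cohorts, gene-set collections and interaction graphs with known ground
    truth so the whole pipeline is testable end to end without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
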