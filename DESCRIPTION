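Package: crosstx
Title: Cross-Tissue Transcriptome Imputation from Blood Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains and evaluates principal-component regression models that
    impute target-tissue (e.g. lung) gene-expression profiles from blood
    transcriptomes measured in paired samples. Provides per-gene five-fold
    cross-validation with squared-correlation accuracy and Benjamini-Hochberg
    gene selection, Fisher-z replication testing against an independent paired
    dataset, RNA-seq normalization utilities (CPM, low-expression filtering,
    log2, quantile normalization, trimmed-mean-of-M-values scaling factors,
    location/scale batch adjustment), covariate-adjusted differential
    expression with log2-fold-change concordance against a reference table,
    and a paired-tissue simulator with known shared latent structure for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    edgeR,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
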