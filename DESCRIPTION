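Package: landmiR
Title: Mature miRNA Expression Imputation from Landmark-Gene Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts mature-miRNA expression profiles from the expression of
    977 L1000 landmark genes with a compact feed-forward regression network
    (batch normalization, ReLU, dropout, SGD with early stopping), trained on
    paired mRNA/miRNA bulk profiles. Includes readers for delimited, Matrix
    Market and AnnData (.h5ad) expression matrices, landmark-panel alignment
    and normalization (log-CPM, per-gene z-scoring, cell quality control),
    per-miRNA and per-sample evaluation metrics (PCC, MSE, RMSE, R squared),
    pseudo-bulk pooling (cell-type averages and bootstrap pools) for
    single-cell inputs, a sparsity and feature-ablation stress-test suite
    (uniform masking, Poisson-based expression-dependent dropout, multinomial
    UMI down-sampling), expected-gradients SHAP attribution with hub-miRNA
    selection and edge-network export, Wilcoxon differential-expression
    statistics, and a synthetic paired-expression generator so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    Matrix,
    jsonlite,
    rhdf5
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
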