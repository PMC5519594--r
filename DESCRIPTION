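Package: ilrmr
Title: Weighted Low-Rank Matrix Recovery for miRNA-Disease Association Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts missing entries of a binary miRNA-disease association
    matrix by decomposing it into a low-rank score matrix plus a sparse error
    matrix (robust principal component analysis), where the elementwise
    sparsity penalty is weighted by a similarity-derived confidence matrix.
    The weighted recovery problem is solved with the exact augmented Lagrange
    multiplier method. Includes cosine-based similarity construction and its
    integration with miRNA functional, disease semantic and miRNA family
    information; leave-one-out, mask-ratio and isolated-disease evaluation
    protocols with ROC/AUC and precision-recall summaries; a synthetic network
    generator with planted low-rank structure; and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
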