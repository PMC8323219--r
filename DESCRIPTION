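Package: fundusgcn
Title: Multi-Label Classification of Fundus Lesions with a Graph
    Convolutional Label Head
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects multiple co-occurring retinal lesions (laser scars,
    drusen, enlarged cup-disc ratio, hemorrhages, arteriosclerosis,
    microaneurysms, hard and soft exudates) in colour fundus photographs.
    A label-dependency graph is estimated from annotation co-occurrence
    (conditional probabilities, thresholded and re-weighted), label word
    embeddings are propagated through a two-layer graph convolutional
    network to produce one linear classifier per lesion, and the
    classifiers are applied to convolutional image features trained
    end-to-end with stochastic gradient descent. Includes the full
    micro/macro F1, per-class accuracy and rank-based AUC evaluation
    suite, and a synthetic fundus-image generator with closed-form label
    co-occurrence so every component is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
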