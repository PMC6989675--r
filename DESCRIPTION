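Package: graspforce
Title: Tuning and Similarity-Space Analysis of Grasping-Force
    Representation Across Volitional States
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing how volitional state (observing,
    imagining, or attempting an action) modulates grasping-force
    representation in intracortical neural features.  Provides a synthetic
    session generator with known ground-truth tuning, spike-band feature
    extraction (threshold-crossing counts and spike-band power),
    heteroskedastic one-way (Welch) and factorial (Johansen) ANOVA tuning
    classification with Benjamini-Hochberg correction, cosine-dissimilarity
    similarity-space analysis with an exact-gradient t-SNE embedding, and
    permutation-calibrated cross-validated LDA decoding over sliding and
    growing analysis windows.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    car,
    data.table,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    cluster,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
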