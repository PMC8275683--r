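Package: implinet
Title: Boolean Implication Networks for Disease-Continuum Modeling
Version: 0.1.0
Authors@R:
    person("BoNE", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds Boolean implication networks from gene-expression
    matrices. Each gene is binarized with a one-step (StepMiner) fit,
    every gene pair is classified into one of six Boolean implication
    relations using a sparse-quadrant statistic, mutually equivalent
    genes are grouped into clusters, and the clusters form a directed
    network oriented from healthy toward disease. Continuum paths
    through the network yield composite per-sample scores that order
    samples along the disease continuum; paths are selected by linear
    regression against sample labels and evaluated with ROC-AUC and
    Fisher exact tests. Includes drug-target vetting rules
    (dual-path membership plus a strong anchor implication), an
    organoid barrier-response (TEER) classifier, and a seeded
    synthetic-cohort generator with planted Boolean structure for
    end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
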