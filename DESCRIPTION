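Package: seqaffinity
Title: Sequence-Based Prediction of Protein-Protein Binding Affinity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the binding free energy of protein-protein complexes
    from chain sequences alone. Provides per-chain sequence descriptors
    (amino-acid composition, averaged BLOSUM62 and PSSM profiles,
    physicochemical indices, and a composite autocorrelation/CTD/
    sequence-order/pseudo-composition set), Smith-Waterman, local-alignment
    and (k,m)-mismatch string kernels with positive-semidefinite correction,
    complex-level feature and kernel lifting, linear, support-vector and
    random-forest regression with grid-search model selection, a
    sequence-homology nearest-neighbour baseline, and leave-one-complex-out
    cross-validation with RMSE and Pearson correlation reporting. A seeded
    synthetic-complex generator makes every stage testable without external
    databases.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    kernlab,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
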