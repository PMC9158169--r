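Package: hmpi
Title: Hybrid Sequence-Structure Deep Learning for Promoter Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Trainable toolkit for promoter identification that couples a
    convolutional sequence branch (PSFN) supervised by a joint
    cross-entropy plus centre loss with a densely linked fully connected
    branch (DSPN) operating on a twelve-property dinucleotide structural
    profile encoding of the same sequence, and fuses the two feature sets
    in a hybrid classifier (HMPI). Includes imbalance-aware variants for
    sigma-factor subtype identification via ADASYN oversampling in
    transferred feature space (HMPIat) and label smoothing regularization
    (HMPIlsr), a bundled dinucleotide structural property table, FASTA
    input handling, stratified data splitting, standard Sn/Sp/Acc/Mcc
    evaluation, and a synthetic planted-motif sequence generator so the
    full pipeline is testable without external downloads. The network
    engine (1-D convolution, dense, batch normalization, dropout, Adam)
    is implemented natively in R.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
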