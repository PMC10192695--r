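Package: ictalnet
Title: Time-Frequency and Directed Brain-Network Characterization of
    Epileptic EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: End-to-end characterization of multichannel scalp EEG in the
    ictal (seizure) and interictal states. Signals are decomposed by
    empirical mode decomposition and mapped to Hilbert spectra and marginal
    spectra for band-energy analysis and image-based classification with a
    small convolutional network; directed functional brain networks are
    inferred channel-pairwise by symbolic transfer entropy, summarized by
    graph metrics (mean shortest path, clustering, global efficiency,
    Laplacian-eigenratio synchronizability), and used as coupling matrices
    for Kuramoto phase-oscillator simulations of seizure synchronization.
    Includes a synthetic-EEG generator with known ground-truth coupling for
    validation, EDF input/output, and a reproducible pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    igraph,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
NeedsCompilation: yes
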