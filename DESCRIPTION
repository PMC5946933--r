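Package: grainAcoustics
Title: Acoustic Monitoring of Stored-Product Insect Activity Under
    Hermetic Storage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting and quantifying stored-product insect
    activity from substrate vibration recordings, and for analysing the
    oxygen-depletion dynamics of hermetically sealed grain. Detects
    brief (1-10 ms) sound impulses in 44.1 kHz recordings, classifies
    them against averaged spectral profiles of verified insect sounds by
    least-squares matching, groups matched impulses into bursts, and
    computes burst-rate activity measures with an infestation-likelihood
    threshold. A hermetic-storage layer computes oxygen budgets and
    depletion-rate statistics, fits log-transformed per-insect activity
    regressions against oxygen depletion, and evaluates grain quality
    (count-and-weigh weight loss, germination capacity). A synthetic-data
    module generates ground-truthed recordings and experiment tables so
    the whole pipeline is testable without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
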