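Package: hostsex
Title: Host Sex Inference from Metagenomic Read Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers the chromosomal sex of the host organism from shotgun
    metagenomic sequencing data using only per-chromosome mapped-read counts
    (the 'samtools idxstats' format). Two normalized coverage statistics are
    computed per sample: Rx, the mean ratio of sex-chromosome coverage to
    each autosome's coverage, and Ry, the fraction of sex-chromosome reads
    mapping to the heterogametic chromosome. A two-class Gaussian kernel
    density classifier trained on multinomial count simulations converts
    (Rx, Ry) into Bayesian posterior probabilities for each sex, abstaining
    ('uncertain') when the maximum posterior falls below a threshold.
    Supports both XY and ZW heterogametic sex-determination systems, ships
    a count-level read simulator for training and benchmarking, and
    includes precision/recall evaluation with a reject option.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
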