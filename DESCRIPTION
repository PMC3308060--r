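Package: excap
Title: Evaluation of Hybrid-Capture Exome Sequencing Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for evaluating solution hybrid-capture (exome) sequencing
    experiments. Implements lane-level read-pair processing (adapter
    read-through clipping, proper-pair and mapping-quality filters, PCR
    duplicate removal, probe-overlap filtering, mate-overlap collapsing with
    base-quality recalibration), sample-level Bayesian diploid consensus
    genotype calling with Phred-scaled consensus qualities, capture
    performance metrics (coverage breadth and uniformity, enrichment score,
    insert-size distributions, replicate depth correlation), genotype
    concordance scoring against gold standards (sensitivity, false discovery
    rate, transition/transversion ratio), and gene-level coverage reports
    with coding-effect classification. A synthetic capture-experiment
    generator with known diploid truth supports end-to-end validation
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
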