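Package: mltrim
Title: Maximum-Likelihood Quality and Homopolymer Trimming of Sequencing Reads
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Unsupervised trimming of high-throughput sequencing reads.
    For each read, the best pair of cut-points delimiting a central
    informative segment framed by two unreliable segments is found by
    maximum likelihood, under a probability-phred model in which a single
    threshold parameter defines the minimal phred score considered
    informative and a cubic Bezier spline extends the probability curve to
    1 at phred 45.  The same segmentation framework trims homopolymer
    (poly-N) stretches from read extremities.  Includes streaming FASTQ and
    gzip FASTQ readers and writers with synchronized paired-end handling, a
    synthetic-read generator with planted cut-points for validation, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    parallel,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
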