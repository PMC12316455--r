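Package: teloend
Title: Telomere Terminal-End Analysis for END-seq and S1-END-seq Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Classifies single-end sequencing reads from END-seq and S1-END-seq
    libraries into G-rich and C-rich telomeric reads by consecutive-repeat
    scanning, quantifies the distribution of the chromosome 5'-terminal hexamer
    over its six cyclic permutations together with per-position information
    content, compares distributions by Kullback-Leibler divergence against
    in-silico canonical/randomized mixtures to estimate the canonical-end
    fraction, inverts the C-strand read fraction of S1-END-seq data into a
    minimum number of internal single-stranded DNA regions per chromosome end
    (an ALT signature), and scans for variant telomeric repeats near read 5'
    ends. Includes a parametric synthetic-library simulator with a ground-truth
    sidecar so every analysis stage is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
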