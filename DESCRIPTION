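Package: telcontent
Title: Telomeric DNA Content Estimation from Whole-Genome Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates telomeric DNA content from whole-genome sequencing
    reads by counting reads that contain the exact telomeric repeat
    (TTAGGG)4 or its reverse complement (CCCTAA)4, normalizing the count by
    average genomic coverage, and summarizing tumor versus matched-normal
    change as a log2 ratio (delta-T). Cohort delta-T values are clustered
    with a Gaussian mixture model selected by the Bayesian information
    criterion, and each sample is called as telomere gain, loss, or no
    change from one-sided component tail probabilities. Includes rank-based
    association tests of mutation and structural-variation burden across
    telomere-status groups, and seeded simulators for synthetic read sets
    and cohort delta-T vectors with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
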