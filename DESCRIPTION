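Package: methcooc
Title: Methylation Co-Occurrence Pattern Analysis for Targeted Bisulfite Amplicon Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps bisulfite-converted amplicon reads to small reference regions
    in converted space, calls per-read CpG methylation with conversion-rate and
    identity quality control, groups reads into methylation co-occurrence
    patterns (epialleles) scored by a one-sided proportion Z-test against an
    observed-pattern baseline, tests pairwise CpG co-methylation dependence by
    Pearson chi-square, calls sequence variants from mismatch pileups and flags
    candidate allele-specific methylation by methylation-level category rules,
    and renders results as fixed-width text reports, pattern figures and UCSC
    Genome Browser custom tracks. Includes a synthetic read simulator with
    known truth for end-to-end validation and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
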