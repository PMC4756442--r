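Package: resvkit
Title: Resequencing Toolkit for SNPs, Indels, Copy Number and Large Deletions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analyses paired-end resequencing alignments of a target genome
    against a reference genome. Calls SNPs and indels from filtered pileups
    with a binomial significance test, detects copy-number variants and
    presence/absence variants from windowed depth-of-coverage ratios using
    circular-binary-segmentation-style changepoint search with explicit
    copy-number loss/gain inequalities, discovers large deletions from
    discordant insert sizes with split-read breakpoint refinement by native
    local alignment, annotates transcript-level consequences (amino-acid
    changes, premature or lost stop codons, frameshifts), and ships a
    structural-variant genome and read simulator with an evaluation module
    (positive predictive value, sensitivity, breakpoint-error and
    copy-number-recovery statistics) so the whole pipeline can be validated
    against a known truth set.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    data.table,
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings,
    BiocGenerics,
    IRanges
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
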