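Package: mirprof
Title: Small RNA Sequencing Processing and Isomir-Resolved miRNA
    Expression Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A complete small-RNA sequencing workflow from raw multiplexed
    reads to differential-expression statistics. Reads FASTQ, SCARF and
    tab-delimited tag-count input, demultiplexes on 6-nt barcodes, trims the
    ligated 3' adapter by its 8-nt prefix with a mismatch budget, applies the
    15-32 nt length rules, collapses identical sequences to counted tags, and
    places tags on a genome with up to two mismatches classifying each into
    Eland-style uniqueness strata (U0/U1/U2/R/NM). Mature miRNA 5p/3p arm
    loci are derived from precursor annotation, with the missing arm inferred
    from hairpin reflection and the Dicer 2-nt overhang. Uniquely aligned
    tags are assigned to transcripts by a 50 percent overlap rule and
    quantified at isomir resolution, with three per-transcript expression
    summaries, tpm scaling and a square-root variance-stabilizing transform.
    Statistics cover Welch and moderated t differential expression with
    Benjamini-Hochberg control and fold/abundance filters, and a permutation
    global test on each miRNA's isomir complement with per-isomir
    contributions and Holm-corrected subset detection. A synthetic-library
    generator with a full truth table makes every stage testable without
    sequencer output; BED and WIG tracks are written for genome browsers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    methods,
    purrr,
    Rcpp,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
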