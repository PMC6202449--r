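Package: magcurate
Title: Curation Toolkit for Metagenome-Assembled Genome Bins
Version: 0.1.0
Authors@R: person("Maintainers", "magcurate", email = "maint@example.org",
    role = c("aut", "cre"))
Description: Computations around a composition-and-coverage metagenomic
    binning workflow for non-axenic cultures: binning preset selection from
    ordered bin QC statistics, a pseudo-read homology contamination screen,
    tetranucleotide-frequency and coverage diagnostics for the loss of
    multi-copy rRNA operon contigs during binning, a completeness-normalized
    k-mer identity between bins of unequal completeness, bin accounting and
    summary statistics in the exact quantile dialect of the source tables,
    and a seeded synthetic-community generator that makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
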