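## Internal helpers shared across modules.

#' @importFrom stats median rnorm runif rgamma sd pt cor setNames dist
#' @importFrom utils read.delim write.table head
#' @importFrom methods is
NULL

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards (so library code never clobbers user RNG).
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# Deterministic sub-seed derivation; stays below .Machine$integer.max.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

revcomp_chr <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                                   collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' Locate a packaged fixture file
#'
#' Returns the path of one of the plain-text data files shipped with the
#' package (the transcribed bin QC and SSU rRNA tables, and the taxonomy
#' lineage map used for affiliation and phylum grouping).
#'
#' @param name One of `"table3"`, `"table4"`, `"taxonomy"`.
#' @return Absolute file path.
#' @export
mag_fixture <- function(name = c("table3", "table4", "taxonomy")) {
  name <- match.arg(name)
  file <- switch(name,
    table3   = "table3.tsv",
    table4   = "table4.tsv",
    taxonomy = "taxon_lineages.tsv")
  path <- system.file("extdata", file, package = "magcurate")
  if (path == "") stop2("fixture not found: ", file)
  path
}
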