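## Pseudo-read contamination screen: a bin is split into non-overlapping
## fixed-length reads (250 nt by default), each read is classified by its
## best homology hit, and the foreign fraction is taken over classified
## reads only (both denominators are reported so either convention is
## recomputable).

#' Split contigs into non-overlapping pseudo-reads
#'
#' Per contig, reads start at offsets 1, window+1, ...; a trailing fragment
#' shorter than the window is discarded unless `keep_tail = TRUE`. Read ids
#' are `"<contig>:<start>"` (1-based).
#'
#' @param contigs Named [Biostrings::DNAStringSet].
#' @param window Read length in nt (default 250).
#' @param keep_tail Keep the short trailing fragment?
#' @return A named [Biostrings::DNAStringSet] of pseudo-reads.
#' @export
split_pseudoreads <- function(contigs, window = 250L, keep_tail = FALSE) {
  stopifnot(window >= 1)
  lens <- Biostrings::width(contigs)
  out_ids <- character(0); out_seq <- character(0)
  seqs <- as.character(contigs)
  for (i in seq_along(contigs)) {
    n_full <- lens[i] %/% window
    starts <- if (n_full > 0) (seq_len(n_full) - 1L) * window + 1L else integer(0)
    ends <- starts + window - 1L
    if (keep_tail && lens[i] %% window > 0) {
      starts <- c(starts, n_full * window + 1L)
      ends <- c(ends, lens[i])
    }
    if (length(starts) == 0) next
    out_ids <- c(out_ids, sprintf("%s:%d", names(contigs)[i], starts))
    out_seq <- c(out_seq, substring(seqs[i], starts, ends))
  }
  Biostrings::DNAStringSet(setNames(out_seq, out_ids))
}

#' Classify one pseudo-read from its homology hits
#'
#' Best-hit rule: maximum bitscore, ties broken by minimum e-value, then by
#' input order. With `lca = TRUE` the longest common taxon-path prefix of
#' all hits is returned instead (an alternative parser convention; neither
#' rule is claimed to replicate any specific external parser).
#'
#' @param hits data.frame of hits for ONE read (may be empty), as from
#'   [read_hits()].
#' @param lca Use the lowest-common-ancestor rule instead of best hit.
#' @return Character vector of taxon ranks, or `NULL` when unclassified.
#' @export
classify_read <- function(hits, lca = FALSE) {
  if (is.null(hits) || nrow(hits) == 0) return(NULL)
  paths <- split_taxon_path(hits$taxon_path)
  if (lca) {
    pre <- paths[[1]]
    for (p in paths[-1]) {
      k <- 0L
      while (k < min(length(pre), length(p)) && pre[k + 1] == p[k + 1])
        k <- k + 1L
      pre <- pre[seq_len(k)]
      if (length(pre) == 0) return(NULL)
    }
    return(pre)
  }
  o <- order(-hits$bitscore, hits$evalue)
  paths[[o[1]]]
}

rank_index <- function(rank) {
  if (is.numeric(rank)) return(as.integer(rank))
  idx <- c(domain = 1L, phylum = 2L, class = 3L, order = 4L, family = 5L,
           genus = 6L, species = 7L)
  if (!rank %in% names(idx)) stop2("unknown rank: ", rank)
  idx[[rank]]
}

#' Screen a bin for foreign pseudo-reads
#'
#' Each classified read is *self* when its taxon path contains `self_taxon`
#' at or below the comparison rank, otherwise *foreign*. The foreign
#' percentage is taken over classified reads only; with zero classified
#' reads it is `NA`, not 0.
#'
#' @param read_ids Character vector of pseudo-read ids of the bin.
#' @param hits Hit table data.frame (all reads pooled), as from
#'   [read_hits()].
#' @param self_taxon The bin's own taxon label.
#' @param rank Comparison rank, name or path index (default `"phylum"`).
#' @param lca Classification rule passed to [classify_read()].
#' @param bin_id Label carried into the result.
#' @return List of class `"screen_result"`: bin_id, n_reads, n_classified,
#'   n_self, n_foreign, foreign_pct, breakdown (named counts by classified
#'   taxon at the comparison rank).
#' @export
screen_bin <- function(read_ids, hits, self_taxon, rank = "phylum",
                       lca = FALSE, bin_id = NA_character_) {
  stopifnot(is.character(self_taxon), nzchar(self_taxon))
  ri <- rank_index(rank)
  hits <- hits[hits$query_id %in% read_ids, , drop = FALSE]
  by_read <- split(hits, hits$query_id)
  n_self <- 0L; n_foreign <- 0L
  breakdown <- integer(0)
  for (h in by_read) {
    path <- classify_read(h, lca = lca)
    if (is.null(path)) next
    label <- if (length(path) >= ri) path[ri] else path[length(path)]
    cur <- if (label %in% names(breakdown)) breakdown[[label]] else 0L
    breakdown[label] <- cur + 1L
    at_or_below <- path[seq.int(min(ri, length(path)), length(path))]
    if (self_taxon %in% at_or_below) n_self <- n_self + 1L
    else n_foreign <- n_foreign + 1L
  }
  n_classified <- n_self + n_foreign
  structure(list(
    bin_id = bin_id,
    n_reads = length(read_ids),
    n_classified = n_classified,
    n_self = n_self,
    n_foreign = n_foreign,
    foreign_pct = if (n_classified == 0) NA_real_
                  else 100 * n_foreign / n_classified,
    breakdown = breakdown), class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("Contamination screen", if (!is.na(x$bin_id)) paste0("(", x$bin_id, ")"),
      ":", x$n_classified, "of", x$n_reads, "reads classified;",
      x$n_foreign, "foreign",
      if (is.na(x$foreign_pct)) "(foreign % undefined)"
      else sprintf("(%.2f %%)", x$foreign_pct), "\n")
  invisible(x)
}
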