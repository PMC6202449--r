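## Completeness-normalized genomic identity between two bins. Raw k-mer
## containment (shared fraction of the smaller set) systematically
## understates identity when bins are incomplete: two independent samplings
## of ONE genome at completeness cA and cB share, in expectation, a fraction
## c_other of the smaller set's k-mers (where c_other is the completeness of
## the bin NOT providing the containment denominator). Dividing by c_other
## therefore rescales same-genome pairs towards 1 regardless of
## completeness, making bins of unequal completeness comparable.

#' Canonical k-mer set of a contig collection
#'
#' Strand-collapsed (each k-mer is represented by the lexicographic minimum
#' of itself and its reverse complement); windows containing `N` are
#' skipped. `k` must be odd so no k-mer is its own reverse complement.
#'
#' @param contigs Named [Biostrings::DNAStringSet], character vector, or a
#'   single string.
#' @param k Odd k-mer size in 11..31 (default 21).
#' @return Character vector: the canonical k-mer set (unique).
#' @export
kmer_set <- function(contigs, k = 21L) {
  stopifnot(k %% 2 == 1, k >= 11, k <= 31)
  seqs <- if (is.character(contigs)) contigs else as.character(contigs)
  parts <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    starts <- seq_len(L - k + 1L)
    fwd <- substring(s, starts, starts + k - 1L)
    rc_full <- revcomp_chr(s)
    # k-mer starting at i on the forward strand reverse-complements to the
    # k-mer starting at L-k-i+2 on the reverse-complemented sequence
    rev_aligned <- substring(rc_full, L - k + 2L - starts,
                             L + 1L - starts)
    can <- pmin(fwd, rev_aligned)
    can[!grepl("N", fwd, fixed = TRUE)]
  })
  unique(unlist(parts, use.names = FALSE))
}

#' Completeness-normalized genomic identity between two bins
#'
#' Containment is computed on the smaller k-mer set; the expected
#' containment of two independent subsamples of one genome equals the
#' completeness of the other bin (`c_other`), so
#' `normalized_identity = min(1, raw_containment / c_other)`. Symmetric in
#' A and B: swapping flips the containment side and `c_other` together.
#'
#' @param contigs_a,contigs_b Contig sets of the two bins.
#' @param completeness_a,completeness_b Completeness as fractions in (0,1]
#'   (CheckM-style percentages divided by 100; never re-estimated here).
#' @param k k-mer size (default 21).
#' @param bin_a,bin_b Optional labels.
#' @return List of class `"identity_result"` with binA, binB, k, n_kmers_A,
#'   n_kmers_B, n_shared, raw_containment, completeness_A, completeness_B,
#'   normalized_identity.
#' @export
bin_identity <- function(contigs_a, contigs_b, completeness_a,
                         completeness_b, k = 21L,
                         bin_a = "binA", bin_b = "binB") {
  stopifnot(completeness_a > 0, completeness_a <= 1,
            completeness_b > 0, completeness_b <= 1)
  ka <- kmer_set(contigs_a, k)
  kb <- kmer_set(contigs_b, k)
  if (length(ka) == 0 || length(kb) == 0) stop2("empty k-mer set")
  if (length(ka) <= length(kb)) {
    n_shared <- sum(ka %in% kb)
    raw <- n_shared / length(ka)
    c_other <- completeness_b
  } else {
    n_shared <- sum(kb %in% ka)
    raw <- n_shared / length(kb)
    c_other <- completeness_a
  }
  structure(list(binA = bin_a, binB = bin_b, k = as.integer(k),
                 n_kmers_A = length(ka), n_kmers_B = length(kb),
                 n_shared = n_shared, raw_containment = raw,
                 completeness_A = completeness_a,
                 completeness_B = completeness_b,
                 normalized_identity = min(1, raw / c_other)),
            class = "identity_result")
}

#' @export
print.identity_result <- function(x, ...) {
  cat(sprintf(
    "%s vs %s (k=%d): containment %.4f, completeness %.2f/%.2f, normalized identity %.4f\n",
    x$binA, x$binB, x$k, x$raw_containment, x$completeness_A,
    x$completeness_B, x$normalized_identity))
  invisible(x)
}
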