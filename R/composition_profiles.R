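## Tetranucleotide-frequency (TNF) profiles and the two per-contig signals
## that explain rRNA-contig loss during binning: divergence of a contig's
## composition from its bin's centroid, and the ratio of its depth to the
## bin's length-weighted median depth.

# The 136 canonical 4-mers: a 4-mer and its reverse complement share the
# lexicographically smaller label; palindromes are their own canonical form.
canonical_4mers <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      all4 <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), 4)
      rc <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAStringSet(all4)))
      map <- pmin(all4, rc)
      cache <<- list(map = setNames(map, all4), levels = sort(unique(map)))
    }
    cache
  }
})

#' Canonical tetranucleotide frequency vector
#'
#' Slides a width-4 window (step 1) over the sequence; windows containing a
#' non-ACGT character are skipped. Each counted window increments its
#' canonical 4-mer (the lexicographic minimum of the 4-mer and its reverse
#' complement), giving a strand-agnostic 136-dimension profile.
#'
#' @param seq A single sequence: character string, [Biostrings::DNAString],
#'   or a length-1 [Biostrings::DNAStringSet].
#' @return An object of class `"tnf"`: list with `values` (named numeric of
#'   length 136 summing to 1) and `n_windows` (number of counted windows).
#' @export
tnf_vector <- function(seq) {
  if (is(seq, "DNAStringSet")) {
    stopifnot(length(seq) == 1)
    seq <- seq[[1]]
  }
  if (is.character(seq)) seq <- Biostrings::DNAString(seq)
  if (length(seq) < 4) stop2("undefined profile: sequence shorter than 4")
  counts256 <- Biostrings::oligonucleotideFrequency(seq, 4)
  n <- sum(counts256)
  if (n == 0) stop2("undefined profile: no valid 4-mer window")
  can <- canonical_4mers()
  values <- vapply(split(counts256[names(can$map)], can$map), sum, numeric(1))
  values <- values[can$levels] / n
  structure(list(values = values, n_windows = as.integer(n)), class = "tnf")
}

#' @export
print.tnf <- function(x, ...) {
  cat("TNF profile: 136 canonical 4-mers over", x$n_windows, "windows\n")
  print(head(sort(x$values, decreasing = TRUE), 5))
  invisible(x)
}

#' Euclidean distance between two TNF profiles
#'
#' @param a,b Objects of class `"tnf"`.
#' @return Non-negative numeric.
#' @export
tnf_distance <- function(a, b) {
  stopifnot(inherits(a, "tnf"), inherits(b, "tnf"))
  sqrt(sum((a$values - b$values)^2))
}

# Lower weighted median: smallest x whose cumulative weight reaches half the
# total (matches the expand-each-value-by-its-weight convention).
weighted_median <- function(x, w) {
  stopifnot(length(x) == length(w), all(w > 0))
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w)
  half <- sum(w) / 2
  i <- which(cw >= half)[1]
  # even split exactly at a boundary: average with the next value
  if (isTRUE(all.equal(cw[i], half)) && i < length(x)) (x[i] + x[i + 1]) / 2
  else x[i]
}

#' Composition and depth profile of a bin
#'
#' The centroid is the contig-length-weighted mean of member TNF vectors
#' (renormalized to sum to 1); `mean_intra`/`sd_intra` summarize member
#' distances to that centroid, and the depth summary is the median of member
#' depths weighted by contig length. With fewer than 3 members `sd_intra` is
#' `NA` (a downstream z-score is then unavailable, not 0).
#'
#' @param tnfs List of `"tnf"` objects, one per member contig.
#' @param lengths,depths Numeric vectors parallel to `tnfs`.
#' @return List with `centroid` (a `"tnf"`), `mean_intra`, `sd_intra`,
#'   `weighted_median_depth`, `n`.
#' @export
bin_profile <- function(tnfs, lengths, depths) {
  stopifnot(length(tnfs) >= 1, length(lengths) == length(tnfs),
            length(depths) == length(tnfs))
  mat <- vapply(tnfs, function(t) t$values, numeric(136))
  w <- lengths / sum(lengths)
  cen <- as.numeric(mat %*% w)
  cen <- cen / sum(cen)
  centroid <- structure(list(values = setNames(cen, rownames(mat)),
                             n_windows = sum(vapply(tnfs, `[[`, integer(1),
                                                    "n_windows"))),
                        class = "tnf")
  d <- vapply(tnfs, tnf_distance, numeric(1), b = centroid)
  list(centroid = centroid,
       mean_intra = mean(d),
       sd_intra = if (length(d) >= 3) sd(d) else NA_real_,
       weighted_median_depth = weighted_median(depths, lengths),
       n = length(tnfs))
}

#' Per-contig divergence diagnostics against a bin profile
#'
#' `tnf_z` standardizes the contig-to-centroid distance against the bin's
#' intra-bin distance distribution; `coverage_ratio` is the contig depth
#' over the bin's length-weighted median depth. These are the two signals
#' implicated in the loss of collapsed multi-copy rRNA contigs.
#'
#' @param tnf A `"tnf"` profile of the contig.
#' @param depth Contig median depth.
#' @param profile A bin profile from [bin_profile()].
#' @param contig_id,bin_id Optional labels carried into the result.
#' @return One-row data.frame: contig_id, bin_id, tnf_distance, tnf_z,
#'   coverage_ratio (`tnf_z` is `NA` when `sd_intra` is undefined).
#' @export
divergence_report <- function(tnf, depth, profile,
                              contig_id = NA_character_,
                              bin_id = NA_character_) {
  d <- tnf_distance(tnf, profile$centroid)
  z <- if (is.na(profile$sd_intra) || profile$sd_intra == 0) NA_real_
       else (d - profile$mean_intra) / profile$sd_intra
  data.frame(contig_id = contig_id, bin_id = bin_id, tnf_distance = d,
             tnf_z = z,
             coverage_ratio = depth / profile$weighted_median_depth,
             stringsAsFactors = FALSE)
}

# Compute TNF profiles for a whole contig set; returns a named list.
tnf_profiles <- function(contigs) {
  out <- lapply(seq_along(contigs), function(i) tnf_vector(contigs[[i]]))
  names(out) <- names(contigs)
  out
}

#' Divergence report for every binned contig of a metagenome
#'
#' Convenience wrapper: builds each bin's profile and scores every member
#' against it.
#'
#' @param contigs Named [Biostrings::DNAStringSet].
#' @param assignments Named character vector contig_id -> bin_id.
#' @param depths Named numeric vector of contig median depths.
#' @return data.frame of per-contig divergence rows.
#' @export
divergence_table <- function(contigs, assignments, depths) {
  tnfs <- tnf_profiles(contigs)
  lens <- Biostrings::width(contigs)
  names(lens) <- names(contigs)
  bins <- setdiff(unique(assignments), "nobin")
  rows <- lapply(bins, function(b) {
    ids <- names(assignments)[assignments == b]
    prof <- bin_profile(tnfs[ids], lens[ids], depths[ids])
    do.call(rbind, lapply(ids, function(id)
      divergence_report(tnfs[[id]], depths[[id]], prof, id, b)))
  })
  do.call(rbind, rows)
}
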