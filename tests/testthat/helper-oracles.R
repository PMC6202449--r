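# Independent brute-force oracles and shared fixtures for the test suite.

# Dictionary-count TNF oracle: enumerate every width-4 window by hand,
# canonicalize via string reverse-complement, count in an environment.
oracle_tnf <- function(seq) {
  rc1 <- function(s) chartr("ACGTN", "TGCAN",
                            paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  counts <- new.env()
  n <- 0L
  for (i in seq_len(nchar(seq) - 3L)) {
    w <- substr(seq, i, i + 3L)
    if (grepl("[^ACGT]", w)) next
    can <- min(w, rc1(w))
    counts[[can]] <- (if (is.null(counts[[can]])) 0L else counts[[can]]) + 1L
    n <- n + 1L
  }
  vals <- unlist(as.list(counts))
  list(freq = vals / n, n_windows = n)
}

# Linear-interpolation quantile oracle via approx() over the plotting
# positions (independent of the package's closed-form implementation).
oracle_quantile <- function(x, p) {
  x <- sort(x)
  if (length(x) == 1) return(x)
  stats::approx(seq(0, 1, length.out = length(x)), x, xout = p)$y
}

# Brute-force preset comparator: pairwise recursive lexicographic rule,
# written independently of select_preset's filtering loop.
oracle_better <- function(qa, qb) {
  # returns -1 if a better, 1 if b better, 0 tie
  for (d in seq_len(max(nrow(qa), nrow(qb)))) {
    ka <- if (d <= nrow(qa))
      c(qa$contamination[d], qa$strain_heterogeneity[d], -qa$completeness[d])
    else c(Inf, Inf, Inf)
    kb <- if (d <= nrow(qb))
      c(qb$contamination[d], qb$strain_heterogeneity[d], -qb$completeness[d])
    else c(Inf, Inf, Inf)
    ka[is.na(ka)] <- Inf; kb[is.na(kb)] <- Inf
    for (col in 1:3) {
      if (ka[col] < kb[col]) return(-1L)
      if (ka[col] > kb[col]) return(1L)
    }
  }
  0L
}

oracle_select <- function(tabs) {
  best <- names(tabs)[1]
  for (p in names(tabs)[-1]) {
    cmp <- oracle_better(tabs[[best]], tabs[[p]])
    if (cmp > 0) best <- p
    else if (cmp == 0) {
      ord <- binning_presets()$name
      if (match(p, ord) < match(best, ord)) best <- p
    }
  }
  best
}

random_dna <- function(n, with_n = FALSE) {
  alpha <- if (with_n) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
  paste(sample(alpha, n, replace = TRUE), collapse = "")
}

# Memoized demo community so multiple test files can share one simulation.
demo_cache <- new.env()
get_demo <- function(seed = 1L) {
  key <- as.character(seed)
  if (is.null(demo_cache[[key]])) demo_cache[[key]] <- demo_community(seed)
  demo_cache[[key]]
}

# Assignment accuracy of a binning result against truth labels, over
# non-rRNA contigs: fraction recovered in their genome's majority bin.
binning_accuracy <- function(result, truth) {
  ids <- truth$contig_id[!truth$is_rrna_contig]
  a <- result$assignments[ids]
  g <- truth$genome[match(ids, truth$contig_id)]
  tab <- table(a, g)
  tab <- tab[rownames(tab) != "nobin", , drop = FALSE]
  if (nrow(tab) == 0) return(0)
  sum(apply(tab, 2, max)) / length(ids)
}

qc_toy <- function(...) {
  rows <- list(...)
  data.frame(contamination = vapply(rows, `[[`, 0, 1),
             strain_heterogeneity = vapply(rows, `[[`, 0, 2),
             completeness = vapply(rows, `[[`, 0, 3))
}
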