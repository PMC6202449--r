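## Summary statistics and bin accounting in exactly the dialect that
## reproduces the printed study-scale numbers from the packaged QC/rRNA
## fixtures: type-7 linear-interpolation quantiles (the single most
## important dialect decision here), Pearson correlation with a t-based
## two-sided p-value, phylum-group accounting via the packaged lineage map,
## the orthologous-group filter and supermatrix missingness.

#' Type-7 quantile (linear interpolation of order statistics)
#'
#' `h = (n - 1) p + 1`; the result interpolates between the `floor(h)`-th
#' and next order statistics. This is the convention that reproduces the
#' study-scale IQRs from the packaged table.
#'
#' @param values Non-empty numeric vector.
#' @param p Probability in 0..1.
#' @return Numeric quantile.
#' @export
quantile_type7 <- function(values, p) {
  if (length(values) == 0) stop2("empty values")
  stopifnot(p >= 0, p <= 1, !anyNA(values))
  x <- sort(values)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) return(x[n])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}

#' Median / quartile summary with type-7 quantiles
#'
#' @param values Non-empty numeric vector.
#' @return List: n, median, q1, q3, iqr.
#' @export
summary_stats <- function(values) {
  list(n = length(values),
       median = quantile_type7(values, 0.5),
       q1 = quantile_type7(values, 0.25),
       q3 = quantile_type7(values, 0.75),
       iqr = quantile_type7(values, 0.75) - quantile_type7(values, 0.25))
}

#' Pearson correlation with two-sided t-test p-value
#'
#' @param x,y Numeric vectors of equal length >= 3, neither constant.
#' @return List: r, p_value, n.
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0) stop2("constant vector")
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p_value = 2 * pt(-abs(t), df = n - 2), n = n)
}

# Does `taxon`'s lineage pass through `group` (e.g. Proteobacteria)?
in_phylum_group <- function(taxon, group, lineages) {
  l <- lineages[[taxon]]
  !is.null(l) && group %in% l
}

#' Bin and rRNA accounting from QC and rRNA tables
#'
#' Counts the categories of the study-scale accounting: total bins
#' (nature != No), cyanobacterial / microbiome / unclassified bins,
#' microbiome bins by phylum group (via the packaged lineage map; taxa
#' missing from the map count under `other_bacteria` with a warning),
#' nearly complete foreign bins, medium-quality cyanobacterial bins and the
#' rRNA totals.
#'
#' @param qc QC data.frame from [read_qc_table()].
#' @param rrna rRNA data.frame from [read_rrna_table()] (optional).
#' @param lineages Lineage map from [read_taxon_lineages()].
#' @return Named list of integer counts.
#' @export
bin_accounting <- function(qc, rrna = NULL,
                           lineages = read_taxon_lineages()) {
  bins <- qc[qc$nature != "No", , drop = FALSE]
  m <- bins[bins$nature == "M", , drop = FALSE]
  known <- m$taxon %in% names(lineages)
  if (any(!known))
    warning("taxon label(s) not in lineage map, counted as other_bacteria: ",
            paste(unique(m$taxon[!known]), collapse = ", "))
  proteo <- vapply(m$taxon, in_phylum_group, logical(1),
                   group = "Proteobacteria", lineages = lineages)
  bacteroid <- vapply(m$taxon, in_phylum_group, logical(1),
                      group = "Bacteroidetes", lineages = lineages)
  cy <- bins[bins$nature == "C", , drop = FALSE]
  out <- list(
    total = nrow(bins),
    cyanobacterial = nrow(cy),
    microbiome = nrow(m),
    unclassified = sum(bins$nature == "U"),
    proteobacteria = sum(proteo),
    bacteroidetes = sum(bacteroid),
    other_bacteria = sum(!proteo & !bacteroid),
    foreign_complete90 = sum(m$completeness >= 90, na.rm = TRUE),
    cyano_medium_quality = sum(cy$completeness >= 90 &
                                 cy$contamination < 5, na.rm = TRUE))
  if (!is.null(rrna)) {
    out$rrna_predicted <- nrow(rrna)
    out$rrna_direct_from_bin <- sum(rrna$direct_from_bin)
    out$rrna_unaffiliated <- sum(is.na(rrna$affiliated_bin))
  }
  out
}

#' Filter orthologous groups for supermatrix construction
#'
#' Keeps an OG iff it is present in at least `min_organisms` organisms and
#' its mean copy number over the organisms that have it is at most
#' `max_mean_copy`.
#'
#' @param og_counts Matrix or data.frame, OGs in rows and organisms in
#'   columns, entries = gene copy counts (>= 0).
#' @param min_organisms,max_mean_copy Filter thresholds (defaults 62 / 1.1).
#' @return Character vector of kept OG row names.
#' @export
filter_ogs <- function(og_counts, min_organisms = 62, max_mean_copy = 1.1) {
  m <- as.matrix(og_counts)
  stopifnot(all(m >= 0))
  n_org <- rowSums(m >= 1)
  total <- rowSums(m)
  mean_copy <- ifelse(n_org > 0, total / n_org, Inf)
  rownames(m)[n_org >= min_organisms & mean_copy <= max_mean_copy]
}

#' Missing character states of a phylogenomic supermatrix
#'
#' @param present_counts Per-taxon counts of present positions.
#' @param total_positions Number of alignment positions.
#' @return Percentage of missing character states.
#' @export
matrix_missingness <- function(present_counts, total_positions) {
  stopifnot(all(present_counts <= total_positions), total_positions > 0)
  100 * (1 - sum(present_counts) /
           (length(present_counts) * total_positions))
}

#' Full fixture report (summaries, accounting, correlations)
#'
#' Convenience wrapper combining [summary_stats()], [pearson()] and
#' [bin_accounting()] on a QC/rRNA table pair; this is what the `report`
#' CLI subcommand writes out.
#'
#' @param qc QC data.frame.
#' @param rrna rRNA data.frame (optional).
#' @param lineages Lineage map.
#' @return List: accounting, cyano (summaries + correlation), microbiome.
#' @export
curation_report <- function(qc, rrna = NULL,
                            lineages = read_taxon_lineages()) {
  cy <- qc[qc$nature == "C", , drop = FALSE]
  m <- qc[qc$nature == "M", , drop = FALSE]
  list(
    accounting = bin_accounting(qc, rrna, lineages),
    cyano = list(
      completeness = summary_stats(cy$completeness),
      contamination = summary_stats(cy$contamination),
      scaffolds = summary_stats(cy$n_scaffolds),
      coverage_completeness = pearson(cy$coverage_med, cy$completeness)),
    microbiome = list(
      completeness = summary_stats(m$completeness),
      scaffolds = summary_stats(m$n_scaffolds),
      coverage_completeness = pearson(m$coverage_med, m$completeness)))
}
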