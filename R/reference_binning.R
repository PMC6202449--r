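## A deliberately simple composition+coverage binner with five named presets
## (permissive -> strict), the preset-selection procedure over per-preset bin
## QC statistics, a merge advisory, and MIMAG-style quality tiers. The binner
## is a stand-in with the qualitative mechanics of production tools: contigs
## are linked when BOTH their TNF distance and their log2 depth ratio fall
## under the preset thresholds, and clusters are grown by single linkage.

#' The five binning presets
#'
#' Thresholds tighten strictly from `verysensitive` to `superspecific`.
#'
#' @return data.frame with columns name, tnf_threshold,
#'   coverage_log_threshold, min_contig_length, min_bin_length.
#' @export
binning_presets <- function() {
  data.frame(
    name = c("verysensitive", "sensitive", "specific", "veryspecific",
             "superspecific"),
    tnf_threshold = c(0.10, 0.08, 0.06, 0.05, 0.04),
    coverage_log_threshold = c(1.5, 1.2, 1.0, 0.8, 0.6),
    min_contig_length = 2500L,
    min_bin_length = 50000L,
    stringsAsFactors = FALSE)
}

preset_config <- function(preset) {
  if (is.character(preset)) {
    p <- binning_presets()
    row <- p[p$name == preset, ]
    if (nrow(row) != 1) stop2("unknown preset: ", preset)
    return(as.list(row))
  }
  stopifnot(is.list(preset),
            all(c("tnf_threshold", "coverage_log_threshold",
                  "min_contig_length", "min_bin_length") %in% names(preset)))
  preset
}

#' Bin contigs by TNF and coverage under one preset
#'
#' Contigs shorter than `min_contig_length` go straight to `"nobin"`. The
#' rest are clustered by single linkage over the composite link criterion
#' (TNF distance <= `tnf_threshold` AND |log2 depth ratio| <=
#' `coverage_log_threshold`); clusters whose total length falls under
#' `min_bin_length` dissolve to `"nobin"`. Bins are numbered by decreasing
#' total length (`bin1` largest). The result is a partition: every contig
#' maps to exactly one bin or to `"nobin"`.
#'
#' @param contigs Named [Biostrings::DNAStringSet].
#' @param depths Named numeric vector of contig median depths, or a depth
#'   table data.frame.
#' @param preset Preset name or a config list (see [binning_presets()]).
#' @return List of class `"binning_result"`: `preset`, `assignments` (named
#'   character contig_id -> bin_id).
#' @export
bin_contigs <- function(contigs, depths, preset = "specific") {
  cfg <- preset_config(preset)
  if (is.data.frame(depths)) depths <- depth_vector(depths)
  ids <- names(contigs)
  missing_depth <- setdiff(ids, names(depths))
  if (length(missing_depth) > 0)
    stop2("no depth for contig(s): ", paste(head(missing_depth, 5),
                                            collapse = ", "))
  lens <- setNames(Biostrings::width(contigs), ids)
  assignments <- setNames(rep("nobin", length(ids)), ids)
  eligible <- ids[lens >= cfg$min_contig_length]
  if (length(eligible) > 0) {
    tnfs <- tnf_profiles(contigs[eligible])
    n <- length(eligible)
    mat <- vapply(tnfs, function(t) t$values, numeric(136))
    dd <- as.matrix(stats::dist(t(mat)))
    ld <- abs(outer(log2(depths[eligible]), log2(depths[eligible]), "-"))
    link <- dd <= cfg$tnf_threshold & ld <= cfg$coverage_log_threshold
    # single linkage = connected components of the link graph (union-find)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    for (i in seq_len(n - 1)) for (j in which(link[i, ] & seq_len(n) > i)) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
    comp <- vapply(seq_len(n), find, integer(1))
    sizes <- tapply(lens[eligible], comp, sum)
    keep <- names(sizes)[sizes >= cfg$min_bin_length]
    keep <- keep[order(-sizes[keep])]
    for (k in seq_along(keep)) {
      members <- eligible[comp == as.integer(keep[k])]
      assignments[members] <- sprintf("bin%d", k)
    }
  }
  structure(list(preset = if (is.character(preset)) preset else
                   (preset$name %||% "custom"),
                 assignments = assignments),
            class = "binning_result")
}

#' @export
print.binning_result <- function(x, ...) {
  tab <- table(x$assignments)
  cat("Binning (", x$preset, "): ", sum(x$assignments != "nobin"),
      " contigs in ", sum(names(tab) != "nobin"), " bin(s), ",
      sum(x$assignments == "nobin"), " in nobin\n", sep = "")
  invisible(x)
}

# Lexicographic QC key at one bin rank: minimize contamination, then strain
# heterogeneity, then maximize completeness. Missing minimize-fields rank
# worst; missing completeness ranks worst too.
qc_key <- function(rec) {
  c(if (is.na(rec$contamination)) Inf else rec$contamination,
    if (is.na(rec$strain_heterogeneity)) Inf else rec$strain_heterogeneity,
    if (is.na(rec$completeness)) Inf else -rec$completeness)
}

#' Select the best binning preset from per-preset QC tables
#'
#' Presets are compared on the QC statistics of their largest bin, in the
#' order (1) contamination (minimize), (2) strain heterogeneity (minimize),
#' (3) completeness (maximize). Exact ties on the largest bin are broken by
#' the next-largest bin, recursively; a persisting full tie returns the most
#' sensitive of the tied presets (documented order: verysensitive first).
#' The choice is invariant to the order the tables are supplied in.
#'
#' @param qc_tables Named list (preset name -> QC data.frame with
#'   `contamination`, `strain_heterogeneity`, `completeness`; rows ordered by
#'   decreasing bin total length, nobin rows excluded or marked nature "No").
#' @return The selected preset name.
#' @export
select_preset <- function(qc_tables) {
  stopifnot(length(qc_tables) >= 1, !is.null(names(qc_tables)))
  qc_tables <- lapply(qc_tables, function(q) {
    if (!is.null(q$nature)) q <- q[q$nature != "No", , drop = FALSE]
    q
  })
  empty <- vapply(qc_tables, nrow, integer(1)) == 0
  if (any(empty)) {
    warning("excluding preset(s) with empty QC table: ",
            paste(names(qc_tables)[empty], collapse = ", "))
    qc_tables <- qc_tables[!empty]
  }
  if (length(qc_tables) == 0) stop2("no preset with a non-empty QC table")
  sens_order <- binning_presets()$name
  cand <- names(qc_tables)
  depth <- 1L
  max_depth <- max(vapply(qc_tables, nrow, integer(1)))
  while (length(cand) > 1 && depth <= max_depth) {
    keys <- lapply(cand, function(p) {
      q <- qc_tables[[p]]
      if (nrow(q) < depth) c(Inf, Inf, Inf) else qc_key(q[depth, ])
    })
    km <- do.call(rbind, keys)
    best <- rep(TRUE, length(cand))
    for (col in 1:3) {
      m <- min(km[best, col])
      best <- best & km[, col] == m
    }
    cand <- cand[best]
    depth <- depth + 1L
  }
  if (length(cand) > 1) {
    ranked <- match(cand, sens_order)
    cand <- if (all(is.na(ranked))) sort(cand)[1] else
      cand[which.min(replace(ranked, is.na(ranked), Inf))]
  }
  cand
}

#' Advise on merging two complementary bins
#'
#' Merging is recommended only when the bins are complementary in recovered
#' marker genes AND their taxon placements are congruent: both non-root and
#' one an ancestor-or-equal of the other in the packaged lineage map.
#'
#' @param taxon_x,taxon_y Taxon labels of the two bins.
#' @param complementary Logical: marker-gene complementarity.
#' @param lineages Lineage map from [read_taxon_lineages()].
#' @return List with `merge` (logical) and `reason`.
#' @export
merge_advisory <- function(taxon_x, taxon_y, complementary,
                           lineages = read_taxon_lineages()) {
  if (!isTRUE(complementary))
    return(list(merge = FALSE, reason = "bins are not complementary"))
  root_like <- function(t) is.na(t) || t %in% c("", "root", "Unclassified",
                                                "unclassified-root")
  if (root_like(taxon_x) || root_like(taxon_y))
    return(list(merge = FALSE,
                reason = "at least one bin is unclassified (root)"))
  lx <- lineages[[taxon_x]]; ly <- lineages[[taxon_y]]
  if (is.null(lx) || is.null(ly))
    return(list(merge = FALSE, reason = "taxon not in lineage map"))
  k <- min(length(lx), length(ly))
  if (!identical(lx[seq_len(k)], ly[seq_len(k)]))
    return(list(merge = FALSE, reason = "taxon placements not congruent"))
  list(merge = TRUE, reason = "complementary with nested taxon placements")
}

#' MIMAG-style quality tier of a bin
#'
#' Medium quality requires completeness >= 90% and contamination < 5%;
#' high additionally requires an affiliated SSU rRNA gene; anything else is
#' low.
#'
#' @param completeness,contamination Percentages.
#' @param has_affiliated_rrna Logical.
#' @return `"high"`, `"medium"` or `"low"`.
#' @export
quality_tier <- function(completeness, contamination, has_affiliated_rrna) {
  if (is.na(completeness)) stop2("completeness is missing")
  if (is.na(contamination)) stop2("contamination is missing")
  medium <- completeness >= 90 && contamination < 5
  if (medium && isTRUE(has_affiliated_rrna)) "high"
  else if (medium) "medium"
  else "low"
}
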