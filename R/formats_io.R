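## External format readers/writers: FASTA contigs, MetaBAT-style depth tables,
## bin QC tables (CheckM-level statistics), SSU rRNA tables, outfmt-6-like hit
## tables with a trailing taxon-path column, bin membership tables and
## GFF-style rRNA locus lines. All tabular formats are tab-separated UTF-8
## with a header row; missing cells are written as "na" and parsed to NA,
## never to 0.

#' Read contig sequences from a FASTA file
#'
#' Identifiers are taken from the header up to the first whitespace,
#' sequences are uppercased and `U` is mapped to `T`.
#'
#' @param path FASTA file.
#' @return A [Biostrings::DNAStringSet] named by contig id.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop2("no such file: ", path)
  if (file.size(path) == 0) return(Biostrings::DNAStringSet())
  raw <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(raw))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0)
    stop2("duplicate contig id(s): ", paste(dup, collapse = ", "))
  seqs <- chartr("u", "t", toupper(as.character(raw)))
  seqs <- chartr("U", "T", seqs)
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write contig sequences to a FASTA file
#'
#' @param seqs Named [Biostrings::DNAStringSet] (or named character vector).
#' @param path Output file.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' Read a MetaBAT-style per-contig depth table
#'
#' Expected columns: `contigName`, `contigLen`, `totalAvgDepth`, then one
#' column per sample.
#'
#' @param path TSV file.
#' @return A data.frame, one row per contig.
#' @export
read_depth_table <- function(path) {
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("contigName", "contigLen", "totalAvgDepth")
  if (!all(need %in% names(d)))
    stop2("depth table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(d$contigName))
    stop2("duplicate contig in depth table: ",
          d$contigName[duplicated(d$contigName)][1])
  if (any(d$totalAvgDepth < 0)) stop2("negative depth in depth table")
  d
}

#' @rdname read_depth_table
#' @param depth Depth table data.frame.
#' @export
write_depth_table <- function(depth, path) {
  write.table(depth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Extract a named depth vector (contig -> median depth) from a depth table.
depth_vector <- function(depth_table) {
  setNames(depth_table$totalAvgDepth, depth_table$contigName)
}

#' Read a bin QC table (CheckM-level statistics per bin)
#'
#' Schema of the packaged `table3.tsv` fixture: strain, metabat_setting, bin,
#' taxon, phylo_mark, nature (C/M/U/No), n_scaffolds, length_pct,
#' coverage_med, completeness, contamination, strain_heterogeneity. `"na"`
#' cells become `NA`. A `bin_id` column (`"bin<k>"`, or `"nobin"` for nature
#' `No`) is derived.
#'
#' @param path TSV file.
#' @return A data.frame of bin QC records.
#' @export
read_qc_table <- function(path) {
  d <- read.delim(path, na.strings = "na", stringsAsFactors = FALSE,
                  colClasses = "character")
  need <- c("strain", "bin", "taxon", "nature", "n_scaffolds", "length_pct",
            "coverage_med", "completeness", "contamination",
            "strain_heterogeneity")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0)
    stop2("QC table missing column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(d$nature), c("C", "M", "U", "No"))
  if (length(bad) > 0)
    stop2("unknown nature value(s): ", paste(bad, collapse = ", "))
  num <- function(col) {
    x <- d[[col]]
    out <- suppressWarnings(as.numeric(x))
    broken <- which(!is.na(x) & is.na(out))
    if (length(broken) > 0)
      stop2("non-numeric ", col, " at row ", broken[1], ": '", x[broken[1]], "'")
    out
  }
  d$n_scaffolds <- as.integer(gsub(" ", "", d$n_scaffolds))
  for (col in c("length_pct", "coverage_med", "completeness", "contamination",
                "strain_heterogeneity"))
    d[[col]] <- num(col)
  if (any(!is.na(d$completeness) & (d$completeness < 0 | d$completeness > 100)))
    stop2("completeness outside [0,100]")
  d$bin_id <- ifelse(d$nature == "No", "nobin", paste0("bin", d$bin))
  d
}

#' @rdname read_qc_table
#' @param qc QC data.frame as returned by `read_qc_table`.
#' @export
write_qc_table <- function(qc, path) {
  out <- qc[setdiff(names(qc), "bin_id")]
  for (col in names(out)) out[[col]][is.na(out[[col]])] <- "na"
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an SSU rRNA prediction table
#'
#' Schema of the packaged `table4.tsv` fixture: strain, taxon, top_hit,
#' source_bin (the bin the gene was predicted in; `bin0` is the nobin),
#' affiliation (empty when the gene could not be affiliated; a trailing `*`
#' marks genes predicted directly from the affiliated bin), coverage.
#'
#' @param path TSV file.
#' @return A data.frame with `affiliated_bin` (`NA` when absent) and logical
#'   `direct_from_bin`.
#' @export
read_rrna_table <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) stop2("empty rRNA table: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  need <- c("strain", "taxon", "top_hit", "source_bin", "affiliation",
            "coverage")
  if (!identical(header[seq_along(need)], need))
    stop2("rRNA table header must be: ", paste(need, collapse = ", "))
  n <- length(lines) - 1L
  if (n == 0) return(data.frame(strain = character(), taxon_label = character(),
    top_hit = character(), source_bin = character(),
    affiliated_bin = character(), direct_from_bin = logical(),
    coverage = numeric(), stringsAsFactors = FALSE))
  rows <- lapply(seq_len(n), function(i) {
    f <- fields[[i + 1L]]
    # a row whose affiliation cell is empty may lose the trailing separator
    if (length(f) == length(need) - 1L) f <- append(f, "", after = 4L)
    if (length(f) != length(need))
      stop2("malformed rRNA table row at line ", i + 1L)
    f
  })
  m <- do.call(rbind, rows)
  aff <- m[, 5]
  direct <- grepl("\\*$", aff)
  aff <- sub("\\*$", "", aff)
  aff[aff == ""] <- NA_character_
  cov <- suppressWarnings(as.numeric(m[, 6]))
  if (anyNA(cov)) stop2("malformed coverage at line ",
                        which(is.na(cov))[1] + 1L)
  if (any(direct & is.na(aff)))
    stop2("direct-from-bin mark without a bin affiliation")
  data.frame(strain = m[, 1], taxon_label = m[, 2], top_hit = m[, 3],
             source_bin = m[, 4], affiliated_bin = aff,
             direct_from_bin = direct, coverage = cov,
             stringsAsFactors = FALSE)
}

#' @rdname read_rrna_table
#' @param rrna rRNA data.frame as returned by `read_rrna_table`.
#' @export
write_rrna_table <- function(rrna, path) {
  aff <- ifelse(is.na(rrna$affiliated_bin), "",
                paste0(rrna$affiliated_bin,
                       ifelse(rrna$direct_from_bin, "*", "")))
  out <- data.frame(strain = rrna$strain, taxon = rrna$taxon_label,
                    top_hit = rrna$top_hit, source_bin = rrna$source_bin,
                    affiliation = aff,
                    coverage = sprintf("%.2f", rrna$coverage))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tabular homology hit file
#'
#' A 13-column outfmt-6-like dialect: the 12 standard columns (qseqid sseqid
#' pident length mismatch gapopen qstart qend sstart send evalue bitscore)
#' plus a trailing semicolon-separated taxon path. A header line starting
#' with `qseqid` or `query_id` is skipped.
#'
#' @param path TSV file.
#' @return A data.frame with `query_id`, `subject_id`, `evalue`, `bitscore`
#'   and `taxon_path` (semicolon-joined string).
#' @export
read_hits <- function(path) {
  lines <- readLines(path)
  empty <- data.frame(query_id = character(), subject_id = character(),
                      evalue = numeric(), bitscore = numeric(),
                      taxon_path = character(), stringsAsFactors = FALSE)
  if (length(lines) == 0) return(empty)
  off <- 0L
  if (grepl("^(qseqid|query_id)\\t", lines[1])) { lines <- lines[-1]; off <- 1L }
  if (length(lines) == 0) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 13L))
    stop2("expected 13 columns at line ", which(nf != 13L)[1] + off)
  m <- do.call(rbind, fields)
  path_col <- m[, 13]
  if (any(path_col == "")) stop2("empty taxon path at line ",
                                 which(path_col == "")[1] + off)
  ev <- as.numeric(m[, 11])
  if (any(ev < 0)) stop2("negative e-value")
  data.frame(query_id = m[, 1], subject_id = m[, 2], evalue = ev,
             bitscore = as.numeric(m[, 12]), taxon_path = path_col,
             stringsAsFactors = FALSE)
}

split_taxon_path <- function(x) strsplit(x, ";", fixed = TRUE)

#' Read / write a bin membership table
#'
#' Two columns: `contig_id`, `bin_id` (`"nobin"` for rejected contigs).
#'
#' @param path TSV file.
#' @return Named character vector contig_id -> bin_id.
#' @export
read_bins_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("contig_id", "bin_id") %in% names(d)))
    stop2("bins table needs columns contig_id, bin_id")
  if (anyDuplicated(d$contig_id))
    stop2("contig assigned more than once: ",
          d$contig_id[duplicated(d$contig_id)][1])
  setNames(d$bin_id, d$contig_id)
}

#' @rdname read_bins_table
#' @param assignments Named character vector contig_id -> bin_id.
#' @export
write_bins_table <- function(assignments, path) {
  write.table(data.frame(contig_id = names(assignments),
                         bin_id = unname(assignments)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write GFF-style rRNA locus lines
#'
#' Nine standard GFF3 columns, 1-based inclusive coordinates; the taxon label
#' is carried in a `Taxon=` attribute (`"Unclassified"` when absent).
#'
#' @param path GFF file.
#' @return A data.frame with `contig_id`, `start`, `end`, `strand`,
#'   `taxon_label`.
#' @export
read_rrna_gff <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0)
    return(data.frame(contig_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      taxon_label = character(), stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 9L))
    stop2("malformed GFF line ", which(lengths(fields) != 9L)[1])
  m <- do.call(rbind, fields)
  taxon <- sub(".*Taxon=([^;]+).*", "\\1", m[, 9])
  taxon[!grepl("Taxon=", m[, 9])] <- "Unclassified"
  start <- as.integer(m[, 4]); end <- as.integer(m[, 5])
  if (any(start < 1L | end < start)) stop2("invalid GFF coordinates")
  data.frame(contig_id = m[, 1], start = start, end = end, strand = m[, 7],
             taxon_label = taxon, stringsAsFactors = FALSE)
}

#' @rdname read_rrna_gff
#' @param loci Locus data.frame as returned by `read_rrna_gff`.
#' @export
write_rrna_gff <- function(loci, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tmagcurate\trRNA\t%d\t%d\t.\t%s\t.\tTaxon=%s",
                     loci$contig_id, loci$start, loci$end,
                     ifelse(is.na(loci$strand), "+", loci$strand),
                     loci$taxon_label))
  writeLines(lines, path)
  invisible(path)
}

#' Read the packaged taxon lineage map
#'
#' @param path TSV with columns `label`, `lineage` (semicolon path, root
#'   first). Defaults to the packaged map.
#' @return Named list label -> character vector of lineage ranks.
#' @export
read_taxon_lineages <- function(path = mag_fixture("taxonomy")) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  setNames(split_taxon_path(d$lineage), d$label)
}
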