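## Seeded synthetic metagenome generator. Each genome gets its own Markov
## composition (so genomes are separable by TNF), its own coverage level, and
## optionally a multi-copy rRNA operon drawn from a separate genome-
## independent chain. Assembler collapse of repeated operons is hard-wired:
## copies >= 2 emit ONE operon-length contig whose depth is coverage x copies
## -- the mechanism by which real multi-copy rRNA contigs acquire inflated
## coverage and divergent composition and end up unbinned.

#' Specification of one synthetic genome
#'
#' @param name Genome name (unique within a community).
#' @param length Genome length in bp, *including* `rrna_copies` operon
#'   copies.
#' @param coverage True sequencing coverage (depth) of the genome.
#' @param markov_order Order of the background composition chain (0, 1 or 2).
#' @param composition_seed Seed for the genome-specific transition matrix
#'   (two genomes with different seeds get distinguishable TNF profiles).
#' @param rrna_copies Number of rRNA operon copies (0 for none).
#' @param rrna_length Operon length in bp (default 5000).
#' @return A `"genome_spec"` list.
#' @export
genome_spec <- function(name, length, coverage, markov_order = 1L,
                        composition_seed = 1L, rrna_copies = 0L,
                        rrna_length = 5000L) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name),
            length >= 1, coverage > 0, markov_order %in% 0:2,
            rrna_copies >= 0, rrna_length >= 100)
  if (rrna_copies > 0 && length < 10 * rrna_length)
    stop2("genome length must be >= 10 x rrna_length when rrna_copies > 0")
  structure(list(name = name, length = as.integer(length),
                 coverage = coverage, markov_order = as.integer(markov_order),
                 composition_seed = as.integer(composition_seed),
                 rrna_copies = as.integer(rrna_copies),
                 rrna_length = as.integer(rrna_length)),
            class = "genome_spec")
}

# Dirichlet(1) transition rows for an order-m chain over ACGT, drawn under
# `composition_seed` so composition is a property of the spec, not the run.
markov_matrix <- function(markov_order, composition_seed) {
  k <- 4L^markov_order
  with_seed(composition_seed, {
    g <- matrix(rgamma(k * 4L, shape = 1), nrow = k)
    g / rowSums(g)
  })
}

# Sample n bases from an order-m chain with transition matrix P (rows indexed
# by the previous state context).
markov_sample <- function(n, markov_order, P) {
  bases <- c("A", "C", "G", "T")
  u <- runif(n)
  if (markov_order == 0L) {
    cp <- cumsum(P[1, ])
    return(paste(bases[findInterval(u, cp) + 1L], collapse = ""))
  }
  cp <- t(apply(P, 1, cumsum))
  idx <- integer(n)
  m <- markov_order
  # warm-up context drawn uniformly
  idx[seq_len(m)] <- findInterval(runif(m), c(0.25, 0.5, 0.75)) + 1L
  ctx <- 0L
  for (i in seq_len(m)) ctx <- ctx * 4L + (idx[i] - 1L)
  mod <- 4L^(m - 1L)
  for (i in (m + 1L):n) {
    s <- findInterval(u[i], cp[ctx + 1L, ]) + 1L
    idx[i] <- s
    ctx <- (ctx %% mod) * 4L + (s - 1L)
  }
  paste(bases[idx], collapse = "")
}

#' Simulate a genome background sequence
#'
#' Draws `spec$length` bases from the genome-specific Markov chain. The same
#' `(spec, rng_seed)` pair always yields the same string.
#'
#' @param spec A [genome_spec()].
#' @param rng_seed Integer seed for the sequence draw.
#' @param length Override of the number of bases to draw (used internally to
#'   leave room for operon copies).
#' @return A character string over ACGT.
#' @export
simulate_genome <- function(spec, rng_seed, length = spec$length) {
  P <- markov_matrix(spec$markov_order, spec$composition_seed)
  with_seed(rng_seed, markov_sample(length, spec$markov_order, P))
}

# The shared operon chain: order 1, strongly GC-skewed relative to typical
# Dirichlet(1) backgrounds, fixed internal composition seed so every genome
# of a community shares one operon sequence.
rrna_operon_seq <- function(length, rng_seed) {
  P <- markov_matrix(1L, 424243L)
  # sharpen the chain so operon composition diverges from any background
  P <- P^3 / rowSums(P^3)
  with_seed(rng_seed, markov_sample(length, 1L, P))
}

truncnorm_depth <- function(n, mean, cv = 0.05) {
  x <- rnorm(n, mean, cv * mean)
  while (any(x <= 0)) x[x <= 0] <- rnorm(sum(x <= 0), mean, cv * mean)
  x
}

#' Fragment a simulated genome into contigs with depths
#'
#' The background genome (spec length minus the operon copies) is cut at
#' random breakpoints into contigs with lengths uniform in `len_range`.
#' With `rrna_copies >= 2` all operon copies collapse into ONE contig of
#' `rrna_length` whose depth is `coverage * rrna_copies`; with exactly one
#' copy the operon is embedded inside the longest ordinary contig. Ordinary
#' contigs get depth ~ Normal(coverage, cv*coverage) truncated at 0.
#'
#' @param spec A [genome_spec()].
#' @param rng_seed Integer seed.
#' @param len_range Contig length range in bp (default 2.5-200 kb).
#' @param depth_cv Coefficient of variation of the depth noise (default 0.05).
#' @return List with `contigs` (named [Biostrings::DNAStringSet]), `depth`
#'   (depth table data.frame), `truth` (contig_id, genome, is_rrna_contig,
#'   true_coverage) and `rrna` (GFF-style locus data.frame, possibly empty).
#' @export
fragment_and_cover <- function(spec, rng_seed,
                               len_range = c(2500L, 200000L),
                               depth_cv = 0.05) {
  stopifnot(length(len_range) == 2, len_range[1] >= 4,
            len_range[1] <= len_range[2])
  bg_len <- spec$length - spec$rrna_copies * spec$rrna_length
  if (bg_len < len_range[1])
    stop2("contig length range incompatible with genome length: background ",
          bg_len, " bp < min contig length ", len_range[1], " bp")
  genome <- simulate_genome(spec, derive_seed(rng_seed, 1L), length = bg_len)
  with_seed(derive_seed(rng_seed, 2L), {
    # cut into uniform-length pieces; a short trailing remainder is merged
    # into the previous contig
    lens <- integer(0)
    left <- bg_len
    while (left > 0) {
      l <- if (left <= len_range[2]) left
           else sample(seq(len_range[1], len_range[2]), 1L)
      if (left - l < len_range[1] && left - l > 0 &&
          left <= len_range[2] + len_range[1]) l <- left
      lens <- c(lens, min(l, left))
      left <- left - min(l, left)
    }
    ends <- cumsum(lens)
    starts <- ends - lens + 1L
    seqs <- substring(genome, starts, ends)
    ids <- sprintf("%s_c%03d", spec$name, seq_along(seqs))
    depths <- truncnorm_depth(length(seqs), spec$coverage, depth_cv)
    is_rrna <- rep(FALSE, length(seqs))
    true_cov <- rep(spec$coverage, length(seqs))
    rrna <- data.frame(contig_id = character(), start = integer(),
                       end = integer(), strand = character(),
                       taxon_label = character(), stringsAsFactors = FALSE)
    if (spec$rrna_copies == 1L) {
      # a single copy assembles in place: insert the operon into the longest
      # ordinary contig (total emitted length = spec length)
      operon <- rrna_operon_seq(spec$rrna_length, derive_seed(rng_seed, 3L))
      host <- which.max(lens)
      at <- sample(seq_len(lens[host] + 1L), 1L)
      seqs[host] <- paste0(substr(seqs[host], 1L, at - 1L), operon,
                           substr(seqs[host], at, lens[host]))
      lens[host] <- lens[host] + spec$rrna_length
      is_rrna[host] <- TRUE
      rrna <- data.frame(contig_id = ids[host], start = at,
                         end = at + spec$rrna_length - 1L, strand = "+",
                         taxon_label = spec$name, stringsAsFactors = FALSE)
    } else if (spec$rrna_copies >= 2L) {
      # the collapsed repeat contig: one operon copy dominating the contig,
      # with short genome-background flanks (as left by a real assembler) --
      # composition is operon-driven but the flanks tie the contig to its
      # genome of origin
      flank <- max(0L, as.integer(0.1 * spec$rrna_length))
      core <- spec$rrna_length - 2L * flank
      operon <- paste0(
        simulate_genome(spec, derive_seed(rng_seed, 4L), length = flank),
        rrna_operon_seq(core, derive_seed(rng_seed, 3L)),
        simulate_genome(spec, derive_seed(rng_seed, 5L), length = flank))
      rid <- sprintf("%s_rrna", spec$name)
      seqs <- c(seqs, operon)
      ids <- c(ids, rid)
      lens <- c(lens, spec$rrna_length)
      depths <- c(depths, spec$coverage * spec$rrna_copies)
      is_rrna <- c(is_rrna, TRUE)
      true_cov <- c(true_cov, spec$coverage * spec$rrna_copies)
      rrna <- data.frame(contig_id = rid, start = 1L,
                         end = spec$rrna_length, strand = "+",
                         taxon_label = spec$name, stringsAsFactors = FALSE)
    }
    contigs <- Biostrings::DNAStringSet(setNames(seqs, ids))
    list(contigs = contigs,
         depth = data.frame(contigName = ids, contigLen = lens,
                            totalAvgDepth = depths,
                            stringsAsFactors = FALSE),
         truth = data.frame(contig_id = ids, genome = spec$name,
                            is_rrna_contig = is_rrna,
                            true_coverage = true_cov,
                            stringsAsFactors = FALSE),
         rrna = rrna)
  })
}

#' Simulate a whole synthetic community
#'
#' Concatenates per-genome contigs, depth rows, truth rows and rRNA loci;
#' deterministic per seed. When `out_dir` is given, writes `contigs.fasta`,
#' `depth.tsv`, `truth.tsv` and `rrna.gff` there.
#'
#' @param specs List of [genome_spec()] objects with unique names.
#' @param rng_seed Integer seed.
#' @param len_range Contig length range passed to [fragment_and_cover()].
#' @param out_dir Optional output directory.
#' @return List with `contigs`, `depth`, `truth`, `rrna` (as in
#'   [fragment_and_cover()], concatenated over genomes).
#' @export
simulate_community <- function(specs, rng_seed,
                               len_range = c(2500L, 200000L),
                               out_dir = NULL) {
  stopifnot(length(specs) >= 1)
  nm <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop2("duplicate genome names: ",
                               nm[duplicated(nm)][1])
  parts <- lapply(seq_along(specs), function(i)
    fragment_and_cover(specs[[i]], derive_seed(rng_seed, 100L + i),
                       len_range = len_range))
  out <- list(
    contigs = do.call(c, lapply(parts, `[[`, "contigs")),
    depth = do.call(rbind, lapply(parts, `[[`, "depth")),
    truth = do.call(rbind, lapply(parts, `[[`, "truth")),
    rrna = do.call(rbind, lapply(parts, `[[`, "rrna")))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(out$contigs, file.path(out_dir, "contigs.fasta"))
    write_depth_table(out$depth, file.path(out_dir, "depth.tsv"))
    write.table(out$truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_rrna_gff(out$rrna, file.path(out_dir, "rrna.gff"))
  }
  out
}

#' The packaged two-genome demonstration community
#'
#' Two 200 kb genomes with distinct composition seeds, coverages 10 and 40,
#' four rRNA operon copies each, fragmented into 2.5-15 kb contigs. This is
#' the stated world for the end-to-end binning / rRNA-fate checks: the
#' collapsed operon contig of each genome carries ~4x its genome's coverage
#' and operon-specific composition.
#'
#' @param rng_seed Integer seed.
#' @return A community list as from [simulate_community()], plus `specs`.
#' @export
demo_community <- function(rng_seed = 1L) {
  specs <- list(
    genome_spec("genA", length = 200000L, coverage = 10, markov_order = 1L,
                composition_seed = 11L, rrna_copies = 4L),
    genome_spec("genB", length = 200000L, coverage = 40, markov_order = 1L,
                composition_seed = 97L, rrna_copies = 4L))
  out <- simulate_community(specs, rng_seed, len_range = c(2500L, 15000L))
  out$specs <- specs
  out
}
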