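test_that("simulate_genome is deterministic and composition-specific", {
  spec <- genome_spec("g", 1000L, 10, composition_seed = 3L)
  expect_identical(simulate_genome(spec, 7L), simulate_genome(spec, 7L))
  expect_false(simulate_genome(spec, 7L) == simulate_genome(spec, 8L))

  # two composition seeds at 200 kb: between-genome TNF distance exceeds the
  # within-genome distance of two halves of either genome
  sa <- genome_spec("a", 200000L, 10, composition_seed = 1L)
  sb <- genome_spec("b", 200000L, 10, composition_seed = 2L)
  ga <- simulate_genome(sa, 1L); gb <- simulate_genome(sb, 1L)
  d_between <- tnf_distance(tnf_vector(ga), tnf_vector(gb))
  half <- function(g) c(substr(g, 1, 100000), substr(g, 100001, 200000))
  d_within <- max(
    tnf_distance(tnf_vector(half(ga)[1]), tnf_vector(half(ga)[2])),
    tnf_distance(tnf_vector(half(gb)[1]), tnf_vector(half(gb)[2])))
  expect_gt(d_between, d_within)
})

test_that("order-0 chain with uniform bases gives balanced GC at 1 Mb", {
  # binomial bound: GC fraction of 1e6 iid uniform bases is in 0.49..0.51
  # with overwhelming probability
  g <- magcurate:::with_seed(11L, magcurate:::markov_sample(
    1000000L, 0L, matrix(0.25, 1, 4)))
  gc <- (nchar(gsub("[AT]", "", g))) / nchar(g)
  expect_gt(gc, 0.49)
  expect_lt(gc, 0.51)
})

test_that("fragment_and_cover conserves length and collapses operons", {
  spec <- genome_spec("g", 200000L, 10, composition_seed = 4L,
                      rrna_copies = 4L)
  com <- fragment_and_cover(spec, 5L, len_range = c(2500L, 15000L))
  lens <- Biostrings::width(com$contigs)
  is_r <- com$truth$is_rrna_contig
  expect_equal(sum(lens[!is_r]), 200000L - 4L * 5000L)
  expect_equal(sum(lens), 200000L - 3L * 5000L)
  expect_equal(sum(is_r), 1L)

  # collapsed operon contig: depth / median ordinary depth ~ copy number
  r_depth <- com$depth$totalAvgDepth[is_r]
  ratio <- r_depth / median(com$depth$totalAvgDepth[!is_r])
  expect_equal(ratio, 4, tolerance = 0.1)
  expect_equal(com$rrna$contig_id, com$truth$contig_id[is_r])

  com0 <- fragment_and_cover(genome_spec("g", 50000L, 10), 5L,
                             len_range = c(2500L, 15000L))
  expect_false(any(com0$truth$is_rrna_contig))
  expect_equal(nrow(com0$rrna), 0)

  expect_error(
    fragment_and_cover(genome_spec("g", 1000L, 10), 1L,
                       len_range = c(2500L, 5000L)),
    "incompatible")
})

test_that("single-copy operons are embedded in an ordinary contig", {
  spec <- genome_spec("g", 100000L, 10, composition_seed = 4L,
                      rrna_copies = 1L)
  com <- fragment_and_cover(spec, 5L, len_range = c(6000L, 20000L))
  expect_equal(sum(Biostrings::width(com$contigs)), 100000L)
  expect_equal(sum(com$truth$is_rrna_contig), 1L)
  host <- com$rrna$contig_id
  seq <- as.character(com$contigs[[host]])
  expect_equal(substring(seq, com$rrna$start, com$rrna$end),
               magcurate:::rrna_operon_seq(
                 5000L, magcurate:::derive_seed(5L, 3L)))
})

test_that("simulate_community writes deterministic, conserved outputs", {
  specs <- list(genome_spec("a", 60000L, 10, composition_seed = 1L),
                genome_spec("b", 60000L, 30, composition_seed = 2L))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  c1 <- simulate_community(specs, 9L, len_range = c(2500L, 8000L),
                           out_dir = d1)
  c2 <- simulate_community(specs, 9L, len_range = c(2500L, 8000L),
                           out_dir = d2)
  for (f in c("contigs.fasta", "depth.tsv", "truth.tsv", "rrna.gff"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))

  # truth partitions contigs into the two genomes; every contig has a row
  expect_setequal(c1$truth$contig_id, names(c1$contigs))
  expect_setequal(unique(c1$truth$genome), c("a", "b"))

  # a different seed moves breakpoints but conserves per-genome totals
  c3 <- simulate_community(specs, 10L, len_range = c(2500L, 8000L))
  tot <- function(com) tapply(Biostrings::width(com$contigs)[
    match(com$truth$contig_id, names(com$contigs))], com$truth$genome, sum)
  expect_equal(tot(c1), tot(c3))
  expect_false(identical(Biostrings::width(c1$contigs),
                         Biostrings::width(c3$contigs)))

  expect_error(simulate_community(list(specs[[1]], specs[[1]]), 1L),
               "duplicate")
})

test_that("emitted depths recover the specified coverage", {
  spec <- genome_spec("g", 200000L, 25, composition_seed = 6L)
  com <- fragment_and_cover(spec, 3L, len_range = c(2500L, 3500L))
  expect_gte(nrow(com$depth), 50)
  expect_equal(median(com$depth$totalAvgDepth), 25, tolerance = 0.02)
})
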