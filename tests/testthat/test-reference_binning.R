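test_that("preset thresholds tighten monotonically", {
  p <- binning_presets()
  expect_equal(p$name, c("verysensitive", "sensitive", "specific",
                         "veryspecific", "superspecific"))
  expect_true(all(diff(p$tnf_threshold) < 0))
  expect_true(all(diff(p$coverage_log_threshold) < 0))
})

test_that("bin_contigs partitions and respects length/depth gates", {
  com <- get_demo()
  for (preset in c("verysensitive", "superspecific")) {
    res <- bin_contigs(com$contigs, com$depth, preset)
    # partition: every contig maps to exactly one label
    expect_setequal(names(res$assignments), names(com$contigs))
    expect_false(anyNA(res$assignments))
  }
  short <- Biostrings::DNAStringSet(c(tiny = strrep("ACGT", 100)))
  res <- bin_contigs(short, c(tiny = 5), "specific")
  expect_equal(unname(res$assignments["tiny"]), "nobin")

  expect_error(bin_contigs(com$contigs,
                           com$depth[-1, ], "specific"), "no depth")
})

test_that("stricter presets never assign more contigs", {
  com <- get_demo()
  n_assigned <- vapply(binning_presets()$name, function(p)
    sum(bin_contigs(com$contigs, com$depth, p)$assignments != "nobin"),
    integer(1))
  expect_true(all(diff(n_assigned) <= 0))
})

test_that("a one-genome community collapses into a single dominant bin", {
  spec <- genome_spec("solo", 150000L, 20, composition_seed = 8L)
  com <- fragment_and_cover(spec, 2L, len_range = c(2500L, 10000L))
  res <- bin_contigs(com$contigs, com$depth, "veryspecific")
  lens <- Biostrings::width(com$contigs)
  in_bin1 <- sum(lens[res$assignments == "bin1"])
  expect_gte(in_bin1 / sum(lens), 0.95)
})

test_that("select_preset applies the ordered lexicographic rule", {
  # contamination dominates
  expect_equal(select_preset(list(
    sensitive = qc_toy(c(1.0, 0, 95)),
    specific = qc_toy(c(0.5, 50, 80)))), "specific")
  # heterogeneity decides at equal contamination
  expect_equal(select_preset(list(
    sensitive = qc_toy(c(0.5, 10, 95)),
    specific = qc_toy(c(0.5, 0, 80)))), "specific")
  # tie on largest bin broken by the next-largest
  expect_equal(select_preset(list(
    sensitive = qc_toy(c(0.5, 0, 90), c(2.0, 0, 50)),
    specific = qc_toy(c(0.5, 0, 90), c(0.3, 0, 50)))), "specific")
  # full tie -> the more sensitive preset
  expect_equal(select_preset(list(
    superspecific = qc_toy(c(0.5, 0, 90)),
    sensitive = qc_toy(c(0.5, 0, 90)))), "sensitive")
  # empty tables excluded with a warning; all empty is an error
  expect_warning(
    sel <- select_preset(list(sensitive = qc_toy(c(1, 0, 50))[0, ],
                              specific = qc_toy(c(1, 0, 50)))),
    "empty")
  expect_equal(sel, "specific")
  expect_error(suppressWarnings(
    select_preset(list(sensitive = qc_toy(c(1, 0, 50))[0, ]))), "no preset")
})

test_that("select_preset matches the brute-force comparator and is
           order-invariant on enumerated toy tables", {
  vals_c <- c(0, 0.5); vals_h <- c(0, 10); vals_q <- c(80, 95)
  grid <- expand.grid(c1 = vals_c, h1 = vals_h, q1 = vals_q,
                      c2 = vals_c, h2 = vals_h, q2 = vals_q)
  set.seed(7)
  for (i in seq_len(150)) {
    pick <- grid[sample(nrow(grid), 3, replace = TRUE), ]
    tabs <- list(
      sensitive = qc_toy(unlist(pick[1, 1:3]), unlist(pick[1, 4:6])),
      veryspecific = qc_toy(unlist(pick[2, 1:3]), unlist(pick[2, 4:6])),
      superspecific = qc_toy(unlist(pick[3, 1:3]), unlist(pick[3, 4:6])))
    expect_equal(select_preset(tabs), oracle_select(tabs))
    expect_equal(select_preset(rev(tabs)), select_preset(tabs))
  }
})

test_that("merge advisory requires complementarity and nested taxa", {
  lin <- read_taxon_lineages()
  adv <- merge_advisory("Alphaproteobacteria", "Sphingomonadales", TRUE, lin)
  expect_true(adv$merge)
  # unclassified partner blocks the merge
  expect_false(merge_advisory("Sphingomonadales", "Unclassified", TRUE,
                              lin)$merge)
  expect_false(merge_advisory("Alphaproteobacteria", "Sphingomonadales",
                              FALSE, lin)$merge)
  # sibling classes are congruent with neither ancestor nor descendant
  expect_false(merge_advisory("Alphaproteobacteria", "Betaproteobacteria",
                              TRUE, lin)$merge)
})

test_that("quality tiers follow the completeness/contamination/rRNA rule", {
  expect_equal(quality_tier(98.11, 0, TRUE), "high")
  expect_equal(quality_tier(98.11, 0, FALSE), "medium")
  expect_equal(quality_tier(24.14, 1.72, TRUE), "low")
  expect_equal(quality_tier(90.0, 4.99, FALSE), "medium")
  expect_equal(quality_tier(89.99, 0, TRUE), "low")
  expect_equal(quality_tier(95, 5, FALSE), "low")
  expect_error(quality_tier(NA, 0, TRUE), "missing")
})
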