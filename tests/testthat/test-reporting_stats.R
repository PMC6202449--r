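test_that("quantile_type7 evaluates its defining formula", {
  expect_equal(quantile_type7(c(1, 2, 3, 4), 0.25), 1.75)
  expect_equal(quantile_type7(c(9, 1, 5), 0.5), 5)  # odd n: middle statistic
  expect_equal(quantile_type7(c(2, 1), 1), 2)
  expect_error(quantile_type7(numeric(0), 0.5), "empty")
})

test_that("quantile_type7 agrees with interpolation oracles", {
  set.seed(8)
  for (i in 1:200) {
    x <- rnorm(sample(2:30, 1)) * 10
    p <- runif(1)
    expect_equal(quantile_type7(x, p), oracle_quantile(x, p),
                 tolerance = 1e-12)
    expect_equal(quantile_type7(x, p),
                 unname(quantile(x, p, type = 7)), tolerance = 1e-12)
  }
})

test_that("fixture summary statistics reproduce the printed values", {
  qc <- read_qc_table(mag_fixture("table3"))
  cy <- qc[qc$nature == "C", ]
  m <- qc[qc$nature == "M", ]

  s <- summary_stats(cy$completeness)
  expect_equal(s$median, 97.74)
  expect_equal(s$iqr, 4.04)

  s <- summary_stats(cy$contamination)
  expect_equal(s$median, 0.47)
  expect_equal(s$iqr, 0.825)  # printed as 0.83 (half-up rounding)

  s <- summary_stats(cy$n_scaffolds)
  expect_equal(s$median, 238)
  expect_equal(s$iqr, 292)

  s <- summary_stats(m$n_scaffolds)
  expect_equal(s$median, 232)
  expect_equal(s$iqr, 205)
  expect_gte(min(m$n_scaffolds), 53)
})

test_that("pearson matches the covariance oracle and cor.test", {
  set.seed(10)
  for (i in 1:20) {
    x <- rnorm(10); y <- rnorm(10)
    p <- pearson(x, y)
    r_oracle <- mean((x - mean(x)) * (y - mean(y))) / (sd(x) * sd(y)) *
      length(x) / (length(x) - 1)
    expect_equal(p$r, r_oracle, tolerance = 1e-12)
    ct <- cor.test(x, y)
    expect_equal(p$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(p$p_value, ct$p.value, tolerance = 1e-12)
  }
  x <- rnorm(8)
  expect_equal(pearson(x, x)$r, 1)
  expect_equal(pearson(x, -x)$r, -1)
  expect_error(pearson(rep(1, 5), rnorm(5)), "constant")
})

test_that("coverage-completeness correlation of cyanobacterial bins", {
  qc <- read_qc_table(mag_fixture("table3"))
  cy <- qc[qc$nature == "C", ]
  p <- pearson(cy$coverage_med, cy$completeness)
  expect_equal(round(p$r, 2), 0.52)
  expect_lte(p$p_value, 0.05)
})

test_that("bin accounting reproduces the printed inventory", {
  qc <- read_qc_table(mag_fixture("table3"))
  rrna <- read_rrna_table(mag_fixture("table4"))
  acc <- bin_accounting(qc, rrna)
  expect_equal(acc$total, 55)
  expect_equal(acc$cyanobacterial, 15)
  expect_equal(acc$microbiome, 31)
  expect_equal(acc$unclassified, 9)
  expect_equal(acc$proteobacteria, 21)
  expect_equal(acc$bacteroidetes, 5)
  expect_equal(acc$other_bacteria, 5)   # bins classified only to Bacteria
  expect_equal(acc$foreign_complete90, 13)
  expect_equal(acc$cyano_medium_quality, 14)
  expect_equal(acc$rrna_predicted, 38)
  expect_equal(acc$rrna_direct_from_bin, 5)
  expect_equal(acc$rrna_unaffiliated, 13)
  # partition consistency
  expect_equal(acc$cyanobacterial + acc$microbiome + acc$unclassified,
               acc$total)

  empty <- qc[0, ]
  acc0 <- bin_accounting(empty)
  expect_true(all(unlist(acc0) == 0))

  qc$taxon[qc$taxon == "Cytophagales"] <- "Wonderland"
  expect_warning(bin_accounting(qc), "Wonderland")
})

test_that("OG filter enforces organism count and mean copy number", {
  m <- rbind(
    og1 = c(rep(1, 60), 2, 2, 2, rep(0, 1)),   # 63 organisms, 66 copies
    og2 = c(rep(1, 61), rep(0, 3)),            # 61 organisms
    og3 = c(rep(1, 51), rep(2, 13), rep(0, 0)))# 64 organisms, 77 copies
  colnames(m) <- sprintf("org%02d", seq_len(ncol(m)))
  expect_equal(filter_ogs(m), "og1")
  expect_equal(filter_ogs(m, min_organisms = 60, max_mean_copy = 1.3),
               c("og1", "og2", "og3"))
})

test_that("matrix missingness arithmetic", {
  expect_equal(matrix_missingness(c(10, 7), 10), 15.0)
  expect_equal(matrix_missingness(c(10, 10), 10), 0)
  expect_equal(matrix_missingness(c(0, 0), 10), 100)
})
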