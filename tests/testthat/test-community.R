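test_that("read_taxon_table validates and round-trips the TSV dialect", {
  ds <- simulate_dataset(tiny_config(seed = 13))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  tab <- read_taxon_table(file.path(dir, "taxon_table.tsv"))
  expect_s3_class(tab, "taxon_table")
  expect_true(all(abs(rowSums(tab$values) - 1) < 1e-6))
  expect_equal(tab$mode, "proportions")

  # counts auto-normalise with the source mode recorded
  cts <- read_taxon_table(file.path(dir, "counts.tsv"))
  expect_equal(attr(cts, "source_mode"), "counts")
  expect_true(all(abs(rowSums(cts$values) - 1) < 1e-9))

  # schema violations give specific errors
  f <- file.path(dir, "bad.tsv")
  writeLines(c("taxon_id\tlineage\ts1", "t1\ta;b;c;d;e;f;g;h\t1"), f)
  expect_error(read_taxon_table(f), "7 levels")
  writeLines(c("taxon_id\tlineage\ts1\ts2", "t1\ta;b\t0.5\t0.5",
               "t1\ta;c\t0.5\t0.5"), f)
  expect_error(read_taxon_table(f), "duplicate")
  writeLines(c("taxon_id\tlineage\ts1", "t1\ta;b\t-0.5"), f)
  expect_error(read_taxon_table(f), "negative")
})

test_that("clade aggregation is additive, mass-conserving and idempotent", {
  vals <- matrix(c(0.3, 0.3, 0.2, 0.2,
                   0.1, 0.5, 0.15, 0.25), 2, 4, byrow = TRUE,
                 dimnames = list(c("s1", "s2"), paste0("t", 1:4)))
  lin <- c("pA;g1", "pA;g2", "pB;g3", "pB;g4")
  tab <- taxon_table(vals, lin, "proportions",
                     levels = c("phylum", "genus"))
  ph <- aggregate_clade(tab, "phylum")
  expect_equal(unname(ph[, "pA"]), c(0.6, 0.6))
  expect_equal(unname(ph[, "pB"]), c(0.4, 0.4))

  # identity at the table's own level, up to column order
  g <- aggregate_clade(tab, "genus")
  expect_equal(g[, c("g1", "g2", "g3", "g4")], vals,
               ignore_attr = TRUE)

  expect_error(aggregate_clade(tab, "order"), "unknown level")

  # mass conserved at every level of a simulated table (within 1e-9)
  ds <- simulate_dataset(tiny_config(seed = 17))
  for (lv in ds$table$levels) {
    m <- aggregate_clade(ds$table, lv)
    expect_equal(unname(rowSums(m)), unname(rowSums(ds$table$values)),
                 tolerance = 1e-9)
  }

  # paper-mimicking configuration: ~80 genus columns (80 + rare taxa)
  big <- simulate_community(sim_config(seed = 3))
  gm <- aggregate_clade(big$table, "genus")
  expect_equal(ncol(gm), 80L + sim_config()$n_rare_taxa)
})

test_that("unclassified taxa keep explicit placeholder columns", {
  vals <- matrix(c(0.5, 0.5), 1, 2,
                 dimnames = list("s1", c("t1", "t2")))
  tab <- taxon_table(vals, c("pA;g1", "pA"), "proportions",
                     levels = c("phylum", "genus"))
  g <- aggregate_clade(tab, "genus")
  expect_true("unclassified_pA" %in% colnames(g))
  expect_equal(sum(g["s1", ]), 1)
})

test_that("Shannon matches closed forms and the vegan oracle", {
  expect_equal(shannon(rep(1 / 80, 80)), log(80))
  expect_equal(shannon(c(1)), 0)
  expect_equal(shannon(c(0.5, 0.25, 0.25)), 1.0397, tolerance = 1e-4)
  expect_error(shannon(c(0, 0)), "zero")
  expect_error(shannon(c(-0.1, 1.1)), "nonnegative")

  # maximal at uniformity for fixed support
  set.seed(6)
  for (i in 1:10) {
    p <- runif(12); p <- p / sum(p)
    expect_lte(shannon(p), log(12) + 1e-12)
  }
  x <- c(40L, 10L, 5L, 1L, 1L, 0L, 3L)
  expect_equal(shannon(x), unname(vegan::diversity(x, "shannon")))
})

test_that("Chao1 follows the singleton/doubleton formula", {
  expect_equal(chao1(c(5L, 4L, 3L, 3L)), 4)            # no singletons
  expect_equal(chao1(c(rep(3L, 7), 1L, 1L, 2L)), 12)   # S=10, F1=2, F2=1
  expect_equal(chao1(c(1L, 1L, 1L)), 6)                # bias-corrected branch
  expect_error(chao1(c(0.5, 0.5)), "integer")
  # Chao1 >= observed richness, always
  set.seed(11)
  for (i in 1:20) {
    x <- rpois(30, 2)
    expect_gte(chao1(x), sum(x > 0))
  }
  # vegan applies the bias-corrected form unconditionally; the classic
  # F1^2/(2 F2) branch used here must agree with it whenever F2 = 0
  x0 <- c(9L, 5L, 1L, 1L, 1L, 4L)
  expect_equal(chao1(x0), unname(vegan::estimateR(x0)["S.chao1"]))
})

test_that("Good's coverage counts singleton mass", {
  expect_equal(goods_coverage(c(50L, 50L)), 1)
  expect_equal(goods_coverage(c(90L, rep(1L, 10))), 0.9)
  expect_equal(goods_coverage(rep(1L, 7)), 0)
  expect_error(goods_coverage(integer(0)), "empty")
  expect_error(goods_coverage(c(0.2, 0.8)), "integer")
})

test_that("diversity_summary needs counts and reports per sample", {
  ds <- simulate_dataset(tiny_config(seed = 19))
  dv <- diversity_summary(ds$counts)
  expect_equal(nrow(dv), nrow(ds$counts$values))
  expect_true(all(dv$chao1 >= dv$s_obs))
  expect_true(all(dv$coverage >= 0 & dv$coverage <= 1))
  expect_error(diversity_summary(ds$table), "counts")
})
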