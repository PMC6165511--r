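test_that("make_taxonomy builds a proper nested lineage set", {
  cfg <- sim_config(clade_counts = c(phylum = 2L, genus = 4L), seed = 3)
  tx <- make_taxonomy(cfg)
  expect_equal(nrow(tx), 4L)
  parts <- strsplit(tx$lineage, ";")
  expect_true(all(lengths(parts) == 2L))
  expect_true(all(vapply(parts, `[`, "", 1L) %in% c("phylum_01", "phylum_02")))

  # default design: 80 unique genus labels
  tx80 <- make_taxonomy(sim_config(seed = 3))
  expect_equal(nrow(tx80), 80L)
  expect_equal(anyDuplicated(tx80$taxon_id), 0L)
  expect_equal(anyDuplicated(tx80$lineage), 0L)

  # nesting is a proper tree: each clade has exactly one parent prefix
  parts <- strsplit(tx80$lineage, ";")
  for (lvl in 2:5) {
    child <- vapply(parts, `[`, "", lvl)
    parent <- vapply(parts, function(p) paste(p[seq_len(lvl - 1)],
                                              collapse = ";"), "")
    expect_true(all(tapply(parent, child, function(x) length(unique(x))) == 1L))
  }

  # determinism and invalid configs
  expect_identical(make_taxonomy(sim_config(seed = 9)),
                   make_taxonomy(sim_config(seed = 9)))
  expect_error(sim_config(clade_counts = c(phylum = 0L, genus = 4L)),
               "counts")
  expect_error(sim_config(clade_counts = c(phylum = 5L, genus = 4L)),
               "non-decreasing")
})

test_that("simulate_community closes rows, plants rare taxa and dominance", {
  cfg <- tiny_config(seed = 21)
  com <- simulate_community(cfg)
  expect_true(all(abs(rowSums(com$table$values) - 1) < 1e-12))

  # rare taxa occupy exactly rare_prevalence samples
  for (id in com$truth$rare_taxon_ids)
    expect_equal(sum(com$table$values[, id] > 0), cfg$rare_prevalence)
  expect_error(simulate_community(tiny_config(rare_prevalence = 999L)),
               "rare_prevalence")

  # with sample-level noise off and no rare spikes, the two dominant
  # phyla carry exactly the configured expected mass
  cfg0 <- sim_config(abundance_sdlog = 0, n_rare_taxa = 0L, seed = 5)
  com0 <- simulate_community(cfg0)
  ph <- aggregate_clade(com0$table, "phylum")
  dom <- rowSums(ph[, com0$truth$dominant_phyla, drop = FALSE])
  expect_true(all(abs(dom - 0.9) < 1e-9))

  # under the default heavy-tailed world the realised share stays near 0.9
  com1 <- simulate_community(sim_config(seed = 5))
  ph1 <- aggregate_clade(com1$table, "phylum")
  dom1 <- rowSums(ph1[, com1$truth$dominant_phyla, drop = FALSE])
  expect_gt(mean(dom1), 0.75)

  # non-planted genera have zero effect; planted ids exist
  expect_true(all(com$truth$planted_genus_ids %in% colnames(com$table$values)))
  unplanted <- setdiff(names(com$truth$gamma), com$truth$planted_genus_ids)
  expect_true(all(com$truth$gamma[unplanted] == 0))
})

test_that("simulate_kinetics follows the model exactly when noiseless", {
  cfg <- tiny_config(seed = 2, obs_noise_sd = 0, n_planted = 0L)
  ds <- simulate_dataset(cfg)
  tc <- merge(ds$timecourses, ds$kinetics_truth,
              by = c("animal", "season", "diet", "substrate", "fraction"))
  expected <- tc$a + tc$b * (1 - exp(-tc$c * tc$time_h))
  expect_equal(tc$fraction_digested_pct, expected, tolerance = 1e-12)

  # direct evaluation of the model at the printed example point
  expect_equal(5 + 60 * (1 - exp(-0.02 * 24)), 27.873, tolerance = 1e-4)

  # gamma = 0 and sigma = 0: every unit on a substrate shares one curve
  per_unit <- split(tc$fraction_digested_pct,
                    list(tc$substrate, tc$fraction, tc$time_h))
  expect_true(all(vapply(per_unit, function(v) max(v) - min(v), 1) < 1e-12))
})

test_that("observation noise has the configured spread", {
  # Monte-Carlo: pooled residual sd over replicated generations ~ sigma_D
  devs <- unlist(lapply(1:50, function(s) {
    cfg <- sim_config(n_animals = 1L, seasons = "spring", diets = "hay",
                      substrates = "hay", n_planted = 0L, n_rare_taxa = 0L,
                      clade_counts = c(phylum = 2L, genus = 4L),
                      obs_noise_sd = 2, seed = s)
    ds <- simulate_dataset(cfg)
    tc <- merge(ds$timecourses, ds$kinetics_truth,
                by = c("animal", "season", "diet", "substrate", "fraction"))
    tc$fraction_digested_pct - (tc$a + tc$b * (1 - exp(-tc$c * tc$time_h)))
  }))
  expect_equal(sd(devs), 2, tolerance = 0.1)
})

test_that("write_dataset round-trips and is deterministic", {
  cfg <- tiny_config(seed = 31)
  ds <- simulate_dataset(cfg)
  d1 <- withr::local_tempdir()
  man <- write_dataset(ds, d1)
  expect_setequal(names(man$files),
                  c("taxon_table", "counts", "timecourses", "metadata",
                    "kinetics_truth", "ground_truth"))
  expect_equal(man$files$taxon_table$rows, ncol(ds$table$values))

  back <- read_dataset(d1)
  expect_equal(back$table$values[rownames(ds$table$values),
                                 colnames(ds$table$values)],
               ds$table$values, tolerance = 1e-12)
  expect_equal(back$timecourses$fraction_digested_pct,
               ds$timecourses$fraction_digested_pct, tolerance = 1e-12)

  # collision guard and degenerate input
  expect_error(write_dataset(ds, d1), "manifest")
  expect_silent(write_dataset(ds, d1, overwrite = TRUE))
  empty <- ds
  empty$table$values <- ds$table$values[0, , drop = FALSE]
  expect_error(write_dataset(empty, withr::local_tempdir()), "empty")

  # byte-identical regeneration under an identical config
  d2 <- withr::local_tempdir()
  write_dataset(simulate_dataset(tiny_config(seed = 31)), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d2, f)),
                     readLines(file.path(d1, f)), label = f)
  }
})
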