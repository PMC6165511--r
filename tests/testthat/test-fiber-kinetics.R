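hay <- feed_composition(DM = 0.875, NDF = 0.700, ADF = 0.379,
                        lignin = 0.061, N = 0.0756)
straw <- feed_composition(DM = 0.878, NDF = 0.846, ADF = 0.536,
                          lignin = 0.10, N = 0.0359)
t6 <- c(24, 36, 48, 72, 96, 120)

test_that("fraction derivation matches detergent-fiber arithmetic", {
  expect_equal(unname(derive_fractions(hay)["cellulose"]), 0.318)
  expect_equal(unname(derive_fractions(straw)["hemicellulose"]), 0.310)
  # boundary: no cellulose when ADF is all lignin
  all_lig <- feed_composition(DM = 0.9, NDF = 0.5, ADF = 0.2, lignin = 0.2)
  expect_equal(unname(derive_fractions(all_lig)["cellulose"]), 0)
  expect_error(feed_composition(DM = 0.9, NDF = 0.5, ADF = 0.2, lignin = 0.3),
               "lignin")
  expect_error(feed_composition(DM = 0.9, NDF = 0.2, ADF = 0.5, lignin = 0.1),
               "ADF")
})

test_that("noiseless identifiable curves are recovered to 1e-6", {
  for (p in list(c(5, 60, 0.02), c(0, 70, 0.022), c(12, 40, 0.05))) {
    d <- p[1] + p[2] * (1 - exp(-p[3] * t6))
    f <- fit_digestion_curve(t6, d)
    expect_lt(abs(f$a - p[1]), 1e-6)
    expect_lt(abs(f$b - p[2]), 1e-6)
    expect_lt(abs(f$c - p[3]), 1e-6)
    expect_true(f$converged)
    expect_false(f$degenerate)
  }
})

test_that("degenerate and invalid time courses are handled", {
  f <- fit_digestion_curve(t6, rep(40, 6))
  expect_equal(f$a, 40)
  expect_equal(f$b, 0)
  expect_equal(f$c, 0)
  expect_true(f$degenerate)
  expect_error(fit_digestion_curve(c(24, 36), c(10, 20)), "3 observations")
  expect_error(fit_digestion_curve(c(24, 36, 30), c(1, 2, 3)), "increasing")
  expect_error(fit_digestion_curve(t6, c(1, 2, 3, 4, 5, 101)), "\\[0, 100\\]")
})

test_that("fit never loses to the dense brute-force grid", {
  set.seed(77)
  fixtures <- c(
    lapply(1:6, function(i) {
      a <- runif(1, 0, 20); b <- runif(1, 30, 80); cc <- runif(1, 0.005, 0.08)
      pmin(pmax(a + b * (1 - exp(-cc * t6)) + rnorm(6, 0, 3), 0), 100)
    }),
    list(c(20, 35, 30, 50, 45, 60),   # rough, non-monotone data
         rep(40, 6) + c(-1, 1, -1, 1, -1, 1)))
  for (d in fixtures) {
    f <- fit_digestion_curve(t6, d)
    expect_lte(f$rss, grid_rss_oracle(t6, d) + 1e-8)
  }
})

test_that("rate recovery is unbiased under observation noise", {
  # 200 simulated units at c = 0.02, sigma_D = 2
  set.seed(42)
  chat <- replicate(200, {
    d <- pmin(pmax(5 + 60 * (1 - exp(-0.02 * t6)) + rnorm(6, 0, 2), 0), 100)
    fit_digestion_curve(t6, d)$c
  })
  expect_lt(abs(mean(chat) - 0.02), 0.1 * 0.02)
})

test_that("prediction honours intercept, asymptote and monotonicity", {
  f <- fit_digestion_curve(t6, 5 + 60 * (1 - exp(-0.02 * t6)))
  expect_equal(predict_digestion(f, 0), f$a)
  expect_equal(predict_digestion(f, 1e9), f$a + f$b, tolerance = 1e-12)
  expect_error(predict_digestion(f, -1), "negative")
  grid <- predict_digestion(f, seq(0, 200, by = 0.5))
  expect_true(all(diff(grid) >= 0))
  # ext120 consistency holds for every fitted object
  expect_identical(f$ext120, predict_digestion(f, 120))
  # direct evaluation: a=0, b=70, c=0.022 at 120 h
  expect_equal(predict_digestion(list(a = 0, b = 70, c = 0.022), 120),
               65.01, tolerance = 1e-3)
})

test_that("summarize_kinetics assembles the six-response matrix", {
  mk <- function(frac, cc) {
    d <- 5 + 60 * (1 - exp(-cc * t6))
    fit_digestion_curve(t6, d, unit = list(animal = "A1", season = "spring",
                                           diet = "hay", substrate = "hay",
                                           fraction = frac))
  }
  fits <- list(mk("NDF", 0.02), mk("cellulose", 0.018),
               mk("hemicellulose", 0.022))
  Y <- summarize_kinetics(fits)
  expect_equal(dim(Y), c(1L, 6L))
  expect_equal(colnames(Y),
               c("NDF_rate", "NDF_ext120", "cellulose_rate",
                 "cellulose_ext120", "hemicellulose_rate",
                 "hemicellulose_ext120"))
  expect_equal(unname(Y[1, "cellulose_rate"]), fits[[2]]$c)
  expect_equal(unname(Y[1, "NDF_ext120"]), fits[[1]]$ext120)

  # missing cellulose fit: flagged cell, others intact
  Y2 <- summarize_kinetics(fits[c(1, 3)])
  expect_true(is.na(Y2[1, "cellulose_rate"]))
  expect_equal(attr(Y2, "missing"), 2L)
  expect_false(anyNA(Y2[1, c("NDF_rate", "hemicellulose_rate")]))

  expect_error(summarize_kinetics(c(fits, fits[1])), "duplicate")
})

test_that("kinetics fitting closes the loop on simulated data", {
  # noiseless simulation -> fits recover the stored ground truth;
  # planted effects off so no unit rate is floored into the nearly
  # linear (unidentifiable) regime
  cfg <- tiny_config(seed = 8, obs_noise_sd = 0, n_planted = 0L)
  ds <- simulate_dataset(cfg)
  fits <- fit_all_kinetics(ds$timecourses)
  fit_df <- do.call(rbind, lapply(fits, function(f)
    data.frame(f$unit, c_hat = f$c, a_hat = f$a)))
  chk <- merge(fit_df, ds$kinetics_truth,
               by = c("animal", "season", "diet", "substrate", "fraction"))
  expect_equal(chk$c_hat, chk$c, tolerance = 1e-6)
  expect_equal(chk$a_hat, chk$a, tolerance = 1e-5)
})
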