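test_that("algebraic Cook's D equals the leave-one-out refit oracle", {
  x <- c(1, 2, 3, 4); y <- c(1, 2, 3, 10)
  expect_equal(cooks_distances(x, y), loo_cook_oracle(x, y),
               tolerance = 1e-10)

  # property: random instances up to n = 30
  set.seed(123)
  for (i in 1:40) {
    n <- sample(4:30, 1)
    x <- rnorm(n)
    y <- 0.5 + 2 * x + rnorm(n, 0, sample(c(0.1, 1, 5), 1))
    expect_equal(cooks_distances(x, y), loo_cook_oracle(x, y),
                 tolerance = 1e-10)
  }
})

test_that("Cook's D edge cases behave", {
  # perfectly linear response: zero residuals, zero influence
  x <- 1:6
  expect_equal(cooks_distances(x, 2 + 3 * x), rep(0, 6))
  expect_error(cooks_distances(rep(1, 5), rnorm(5)), "constant")
  expect_error(cooks_distances(1:3, 1:3), "at least 4")

  # duplicating an observation at (xbar, yhat(xbar)) leaves the other
  # distances unchanged (it adds no information to the fit)
  set.seed(5)
  x <- rnorm(10); y <- 1 + 2 * x + rnorm(10, 0, 0.5)
  fit <- lm(y ~ x)
  x2 <- c(x, mean(x)); y2 <- c(y, unname(predict(fit, data.frame(x = mean(x)))))
  d_orig <- cooks_distances(x, y)
  d_aug <- cooks_distances(x2, y2)[1:10]
  # residual df changes s2 by (n-2)/(n-1); compare via the refit oracle
  expect_equal(d_aug, loo_cook_oracle(x2, y2)[1:10], tolerance = 1e-10)
  expect_equal(order(d_aug), order(d_orig))

  # leverage-1 observation (taxon in a single sample) is infinitely
  # influential: the LOO refit is rank-deficient
  x <- c(rep(0, 9), 5); y <- c(rnorm(9), 40)
  expect_true(is.infinite(cooks_distances(x, y)[10]))
})

make_filter_fixture <- function(n = 32, seed = 1) {
  # smooth taxa plus one rare taxon present in two samples whose spikes
  # coincide with extreme responses
  set.seed(seed)
  smooth <- matrix(runif(n * 6, 0.05, 0.15), n, 6)
  rare <- rep(0, n); rare[c(3, 17)] <- c(0.6, 0.5)
  vals <- cbind(smooth, rare)
  vals <- vals / rowSums(vals)
  colnames(vals) <- c(paste0("tax", 1:6), "rare1")
  rownames(vals) <- paste0("s", seq_len(n))
  y <- 0.02 + 0.001 * scale(vals[, 1])[, 1] + rnorm(n, 0, 0.0005)
  y[c(3, 17)] <- y[c(3, 17)] + 0.03  # rare spikes drive extreme responses
  list(vals = vals, y = setNames(y, rownames(vals)))
}

test_that("filter_taxa removes the constructed rare taxon at alpha = 0.05", {
  fx <- make_filter_fixture()
  res <- filter_taxa(fx$vals, fx$y, alpha = 0.05)
  rep <- res$report
  expect_true(rep$removed[rep$taxon_id == "rare1"])
  expect_gt(rep$max_cooks_d[rep$taxon_id == "rare1"],
            qf(0.95, 2, nrow(fx$vals) - 2))
  expect_false("rare1" %in% colnames(res$table))
  # removal is driven by the F quantile with df (2, n - 2)
  expect_equal(attr(rep, "threshold"), qf(0.95, 2, 30))
})

test_that("the threshold limit and fixed-df modes work", {
  fx <- make_filter_fixture()
  # alpha -> 0: threshold -> infinity, nothing with finite D is removed
  res0 <- filter_taxa(fx$vals, fx$y, alpha = 1e-15)
  expect_false(any(res0$report$removed))

  # fixed df reproduces a study-specific criterion whatever n is
  res_fixed <- filter_taxa(fx$vals, fx$y, alpha = 0.05, df = c(2, 28))
  expect_equal(attr(res_fixed$report, "df"), c(2, 28))
  expect_equal(attr(res_fixed$report, "threshold"), qf(0.95, 2, 28))
})

test_that("uniform taxa survive and constant taxa are skipped, not removed", {
  set.seed(2)
  n <- 20
  vals <- matrix(runif(n * 5, 0.1, 0.3), n, 5)
  vals <- cbind(vals, 0.07)  # constant-proportion taxon
  vals <- vals / rowSums(vals)
  colnames(vals) <- paste0("t", 1:6)
  rownames(vals) <- paste0("s", 1:n)
  y <- rnorm(n)
  # constant *after* closure is unlikely; force column 6 constant exactly
  vals[, 6] <- 0.1
  res <- filter_taxa(vals, y)
  expect_true(res$report$skipped_constant[6])
  expect_false(res$report$removed[6])
  expect_false(any(res$report$removed))
})

test_that("filtering is order-independent and checks alignment", {
  fx <- make_filter_fixture(seed = 7)
  res <- filter_taxa(fx$vals, fx$y)
  perm <- sample(ncol(fx$vals))
  res_p <- filter_taxa(fx$vals[, perm], fx$y)
  m <- match(res$report$taxon_id, res_p$report$taxon_id)
  expect_equal(res_p$report$removed[m], res$report$removed)
  expect_equal(res_p$report$max_cooks_d[m], res$report$max_cooks_d)

  expect_error(filter_taxa(fx$vals, fx$y[-1]), "missing sample")
  expect_error(filter_taxa(fx$vals, unname(fx$y)[-1]), "length")
})

test_that("censoring a taxon_table keeps or restores closure as asked", {
  ds <- simulate_dataset(tiny_config(seed = 23))
  gm <- ds$table
  y <- setNames(rnorm(nrow(gm$values)), rownames(gm$values))
  res <- filter_taxa(gm, y)
  expect_s3_class(res$table, "taxon_table")
  # by default removed mass is dropped, not redistributed
  if (any(res$report$removed))
    expect_true(any(rowSums(res$table$values) < 1 - 1e-12))
  res_n <- filter_taxa(gm, y, renormalize = TRUE)
  expect_equal(unname(rowSums(res_n$table$values)),
               rep(1, nrow(gm$values)), tolerance = 1e-12)
})
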