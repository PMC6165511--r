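# Independent oracles used across the suite. These deliberately take the
# dumb, exhaustive route so they share no code with the implementation.

# exhaustive grid search for the negative exponential fit:
# a in 0..30 by 0.5, b in 0..100 by 0.5, c in 0..0.1 by 0.0005.
# For fixed c the RSS over the whole (a, b) grid is the quadratic
# sum(d^2) - 2a*S_d - 2b*S_dk + n*a^2 + 2ab*S_k + b^2*S_k2, evaluated
# with outer products, so the 2.5M-point sweep stays fast.
grid_rss_oracle <- function(t, d) {
  a_grid <- seq(0, 30, by = 0.5)
  b_grid <- seq(0, 100, by = 0.5)
  c_grid <- seq(0, 0.1, by = 0.0005)
  n <- length(t)
  sum_d2 <- sum(d^2)
  sum_d <- sum(d)
  best <- Inf
  for (cc in c_grid) {
    k <- 1 - exp(-cc * t)
    s_k <- sum(k); s_k2 <- sum(k^2); s_dk <- sum(d * k)
    rss <- sum_d2 - 2 * outer(a_grid * sum_d, b_grid * s_dk, `+`) +
      n * a_grid^2 + 2 * outer(a_grid, b_grid) * s_k +
      matrix(b_grid^2 * s_k2, length(a_grid), length(b_grid), byrow = TRUE)
    m <- min(rss)
    if (m < best) best <- m
  }
  best
}

# leave-one-out refit definition of Cook's distance:
# D_i = sum_j (yhat_j - yhat_j^(i))^2 / (p * s^2), p = 2
loo_cook_oracle <- function(x, y) {
  n <- length(x)
  full <- lm(y ~ x)
  yhat <- fitted(full)
  s2 <- sum(residuals(full)^2) / (n - 2)
  vapply(seq_len(n), function(i) {
    fi <- lm(y[-i] ~ x[-i])
    yhat_i <- coef(fi)[1] + coef(fi)[2] * x
    sum((yhat - yhat_i)^2) / (2 * s2)
  }, numeric(1))
}

# latent-variable data with known intrinsic dimension: X spans exactly an
# A-dimensional subspace (so its predictive content is exhausted after A
# components) and Y is driven by the same scores plus small noise
latent_sim <- function(n, p, m, A, noise = 0.05, seed = 1) {
  set.seed(seed)
  Tm <- matrix(rnorm(n * A), n, A)
  X <- Tm %*% matrix(rnorm(A * p), A, p)
  Y <- Tm %*% matrix(rnorm(A * m), A, m) + matrix(rnorm(n * m, 0, noise), n, m)
  list(X = X, Y = Y)
}

# small config for fast end-to-end tests
tiny_config <- function(seed = 1, ...) {
  sim_config(n_animals = 4L,
             clade_counts = c(phylum = 4L, family = 10L, genus = 24L),
             n_rare_taxa = 2L, seed = seed, ...)
}
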