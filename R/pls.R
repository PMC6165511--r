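#' Column standardization with constant-column handling
#'
#' Centers and scales each column to mean 0, sample standard deviation 1
#' (n - 1 denominator). Constant columns cannot be scaled; they are
#' dropped with a warning and recorded so the caller can reconstruct the
#' original layout.
#'
#' @param M numeric matrix with at least 2 rows.
#' @return list with `Z` (standardized matrix), `center`, `scale`
#'   (statistics of the kept columns) and `dropped` (names/indices of
#'   constant columns).
#' @export
standardize <- function(M) {
  M <- as.matrix(M)
  if (nrow(M) < 2L) stop_rf("standardization needs at least 2 rows")
  ctr <- colMeans(M)
  scl <- apply(M, 2L, sd)
  keep <- scl > 0
  if (!all(keep))
    warning(sum(!keep), " constant column(s) dropped during standardization",
            call. = FALSE)
  Z <- sweep(sweep(M[, keep, drop = FALSE], 2L, ctr[keep], `-`),
             2L, scl[keep], `/`)
  list(Z = Z, center = ctr[keep], scale = scl[keep],
       dropped = colnames(M)[!keep] %||% which(!keep))
}

unstandardize <- function(Z, center, scale) {
  sweep(sweep(Z, 2L, scale, `*`), 2L, center, `+`)
}

#' Fit a PLS model by NIPALS
#'
#' Classical NIPALS partial least squares with deflation of both the
#' predictor and response blocks. Inputs are expected to be standardized
#' (see [standardize()]); [pls_regression()] wraps standardization, LOO
#' component selection and fitting. For a single response the first
#' weight vector is exactly proportional to \eqn{X^\top y}. Weight
#' vectors have unit norm and score vectors are mutually orthogonal.
#'
#' @param X n x p predictor matrix (standardized).
#' @param Y n x m response matrix or vector (standardized).
#' @param A number of latent vectors, `1 <= A <= min(n - 1, p)`.
#' @param tol inner-loop convergence tolerance on the score vector.
#' @param max_iter inner-loop iteration cap; exceeding it is an error.
#' @return object of class `pls_fit`: matrices `W` (p x A weights),
#'   `Tm` (n x A scores), `P` (p x A X-loadings), `Q` (m x A Y-loadings),
#'   `ssy` (per-component explained Y sum of squares),
#'   `r2y_cum` (cumulative fraction of Y variance explained, length A),
#'   `coefficients` (p x m, standardized scale) and bookkeeping fields.
#' @export
fit_pls <- function(X, Y, A, tol = 1e-12, max_iter = 10000L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X); m <- ncol(Y)
  if (nrow(Y) != n) stop_rf("X and Y row counts differ")
  if (A < 1L || A > min(n - 1L, p))
    stop_rf("A must lie in [1, min(n - 1, p)] = [1, ", min(n - 1L, p), "]")
  ssy_total <- sum(Y^2)
  if (ssy_total == 0) stop_rf("Y has zero variance")

  W <- matrix(0, p, A, dimnames = list(colnames(X), NULL))
  P <- matrix(0, p, A, dimnames = list(colnames(X), NULL))
  Tm <- matrix(0, n, A, dimnames = list(rownames(X), NULL))
  Q <- matrix(0, m, A, dimnames = list(colnames(Y), NULL))
  ssy <- numeric(A); r2y_cum <- numeric(A)
  ssx_total <- sum(X^2)
  Xa <- X; Ya <- Y
  actual_A <- A
  for (a in seq_len(A)) {
    # X exhausted (rank < A): a further component would divide by a
    # near-zero score norm and amplify rounding noise into Y
    if (sum(Xa^2) <= 1e-16 * ssx_total) { actual_A <- a - 1L; break }
    u <- Ya[, which.max(apply(Ya, 2L, var))]
    t_old <- rep(Inf, n)
    iter <- 0L
    repeat {
      iter <- iter + 1L
      wv <- crossprod(Xa, u)
      nw <- sqrt(sum(wv^2))
      if (nw < 1e-300) { wv <- NULL; break }
      wv <- wv / nw
      tv <- Xa %*% wv
      qv <- crossprod(Ya, tv) / sum(tv^2)
      if (m == 1L) break
      u <- Ya %*% qv / sum(qv^2)
      if (sqrt(sum((tv - t_old)^2)) < tol * sqrt(sum(tv^2))) break
      t_old <- tv
      if (iter >= max_iter)
        stop_rf("NIPALS inner loop failed to converge after ", max_iter,
                " iterations (component ", a, ", |t| = ",
                signif(sqrt(sum(tv^2)), 4), ")")
    }
    if (is.null(wv)) { actual_A <- a - 1L; break }  # X block exhausted
    pv <- crossprod(Xa, tv) / sum(tv^2)
    W[, a] <- wv; Tm[, a] <- tv; P[, a] <- pv; Q[, a] <- qv
    ssy[a] <- sum(qv^2) * sum(tv^2)
    Xa <- Xa - tcrossprod(tv, pv)
    Ya <- Ya - tcrossprod(tv, qv)
    r2y_cum[a] <- 1 - sum(Ya^2) / ssy_total
  }
  if (actual_A == 0L) stop_rf("no usable latent vector: X'Y is zero")
  keep <- seq_len(actual_A)
  W <- W[, keep, drop = FALSE]; P <- P[, keep, drop = FALSE]
  Tm <- Tm[, keep, drop = FALSE]; Q <- Q[, keep, drop = FALSE]
  ssy <- ssy[keep]; r2y_cum <- r2y_cum[keep]
  # regression coefficients on the standardized scale
  B <- W %*% solve(crossprod(P, W), t(Q))
  rownames(B) <- colnames(X); colnames(B) <- colnames(Y)
  structure(list(A = actual_A, A_requested = A, W = W, Tm = Tm, P = P,
                 Q = Q, ssy = ssy, r2y_cum = r2y_cum, coefficients = B,
                 n = n, p = p, m = m),
            class = "pls_fit")
}

#' @export
print.pls_fit <- function(x, ...) {
  cat(sprintf("<pls_fit> %d x %d -> %d response(s), %d latent vector(s), R2Y = %.3f\n",
              x$n, x$p, x$m, x$A, x$r2y_cum[x$A]))
  invisible(x)
}

#' Predict from a `pls_fit` (standardized scale)
#'
#' @param object a [fit_pls()] result.
#' @param newX standardized predictor matrix with the model's columns.
#' @param A number of components to use (default: all fitted).
#' @param ... unused.
#' @return predicted standardized responses (n x m).
#' @export
predict.pls_fit <- function(object, newX, A = object$A, ...) {
  if (A < 1L || A > object$A) stop_rf("A out of fitted range")
  W <- object$W[, seq_len(A), drop = FALSE]
  P <- object$P[, seq_len(A), drop = FALSE]
  Q <- object$Q[, seq_len(A), drop = FALSE]
  B <- W %*% solve(crossprod(P, W), t(Q))
  as.matrix(newX) %*% B
}

#' Leave-one-out PRESS component selection
#'
#' For each candidate component count `A` in `1..A_max`, leaves each
#' sample out once, re-standardizes predictors and responses on the
#' remaining rows (no information leaks from the held-out sample), fits
#' the model, predicts the held-out row, and accumulates the squared
#' prediction error over all responses on the training fold's
#' standardized response scale. The selected `A*` minimizes PRESS; ties
#' resolve to the smaller count. The procedure is fully deterministic.
#'
#' @param X n x p raw predictor matrix.
#' @param Y n x m raw response matrix or vector.
#' @param A_max largest component count to consider; values at or above
#'   `n - 1` are truncated with a warning (each fold fits on `n - 1`
#'   rows).
#' @param restandardize re-standardize inside each fold (default `TRUE`);
#'   set `FALSE` to standardize once on all rows (leaky, for replication
#'   of analyses that did so).
#' @param tol relative slack on the PRESS minimum: the smallest `A` whose
#'   PRESS is within `(1 + tol)` of the minimum is selected, so hairline
#'   improvements from fitting noise never buy an extra latent vector;
#'   `tol = 0` gives the strict argmin (ties still resolve to smaller A).
#' @return list with `A` (selected count) and `press` (named vector of
#'   PRESS by candidate A).
#' @export
loo_select_components <- function(X, Y, A_max = 5L, restandardize = TRUE,
                                  tol = 0.05) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (is.null(colnames(Y))) colnames(Y) <- paste0("y", seq_len(ncol(Y)))
  n <- nrow(X)
  if (n < 3L) stop_rf("LOO selection needs at least 3 samples")
  cap <- min(n - 2L, ncol(X))
  if (A_max > cap) {
    warning("A_max truncated from ", A_max, " to ", cap, call. = FALSE)
    A_max <- cap
  }
  if (!restandardize) {
    sx_all <- standardize(X); sy_all <- standardize(Y)
  }
  press <- setNames(numeric(A_max), paste0("A", seq_len(A_max)))
  for (i in seq_len(n)) {
    if (restandardize) {
      # columns constant within a fold (e.g. rare taxa) drop silently:
      # this is routine during LOO, not a data problem worth a warning
      sx <- suppressWarnings(standardize(X[-i, , drop = FALSE]))
      sy <- suppressWarnings(standardize(Y[-i, , drop = FALSE]))
    } else {
      sx <- list(Z = sx_all$Z[-i, , drop = FALSE], center = sx_all$center,
                 scale = sx_all$scale, dropped = sx_all$dropped)
      sy <- list(Z = sy_all$Z[-i, , drop = FALSE], center = sy_all$center,
                 scale = sy_all$scale, dropped = sy_all$dropped)
    }
    fold_A <- min(A_max, nrow(sx$Z) - 1L, ncol(sx$Z))
    fit <- fit_pls(sx$Z, sy$Z, fold_A)
    x_new <- (X[i, names(sx$center), drop = FALSE] - sx$center) / sx$scale
    y_new <- (Y[i, names(sy$center), drop = FALSE] - sy$center) / sy$scale
    for (A in seq_len(A_max)) {
      Ai <- min(A, fit$A)
      err <- y_new - predict(fit, x_new, A = Ai)
      press[A] <- press[A] + sum(err^2)
    }
  }
  list(A = unname(which(press <= (1 + tol) * min(press))[1L]),
       press = press)
}

#' Variable importance in projection (VIP)
#'
#' \deqn{VIP_j = \sqrt{p \sum_a SSY_a w_{ja}^2 / \sum_a SSY_a}}
#' with \eqn{SSY_a = \|q_a\|^2 \, t_a^\top t_a} the response sum of
#' squares captured by component \eqn{a}. Because every weight vector has
#' unit norm, \eqn{\sum_j VIP_j^2 = p}.
#'
#' @param model a [fit_pls()] result.
#' @return named numeric vector of VIP scores, one per predictor.
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "pls_fit"))
  if (sum(model$ssy) <= 0)
    stop_rf("VIP undefined: model explains no response variance")
  wt2 <- model$W^2
  v <- sqrt(model$p * as.vector(wt2 %*% model$ssy) / sum(model$ssy))
  setNames(v, rownames(model$W))
}

#' Standardize, select components by LOO and fit
#'
#' The user-facing PLS entry point: standardizes `X` and `Y`, selects the
#' latent-vector count by [loo_select_components()] (unless `A` is given),
#' fits the final model on all rows and attaches VIP scores, PRESS and
#' Q2 (cross-validated R2, `1 - PRESS_A / PRESS_0` with `PRESS_0` the
#' LOO error of the column-mean predictor).
#'
#' @param X raw predictor matrix (samples x features).
#' @param Y raw response matrix or vector.
#' @param A fixed component count, or `NULL` to select by LOO PRESS.
#' @param A_max candidate cap for selection.
#' @param restandardize see [loo_select_components()].
#' @return a `pls_model`: the `pls_fit` plus `vip`, `press`, `q2`,
#'   `x_stats`, `y_stats`.
#' @export
pls_regression <- function(X, Y, A = NULL, A_max = 5L, restandardize = TRUE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (is.null(colnames(Y))) colnames(Y) <- paste0("y", seq_len(ncol(Y)))
  sel <- NULL
  if (is.null(A)) {
    sel <- loo_select_components(X, Y, A_max, restandardize)
    A <- sel$A
  }
  sx <- standardize(X); sy <- standardize(Y)
  fit <- fit_pls(sx$Z, sy$Z, min(A, nrow(sx$Z) - 1L, ncol(sx$Z)))
  fit$vip <- vip(fit)
  fit$press <- sel$press
  # PRESS_0: LOO error of predicting each held-out standardized response
  # by the training-fold mean (which is 0 on the training scale but not
  # for the held-out row); equals sum over i of z_i^2 scaled appropriately
  if (!is.null(sel)) {
    n <- nrow(X)
    press0 <- 0
    for (i in seq_len(n)) {
      syi <- suppressWarnings(standardize(Y[-i, , drop = FALSE]))
      zi <- (Y[i, names(syi$center), drop = FALSE] - syi$center) / syi$scale
      press0 <- press0 + sum(zi^2)
    }
    fit$q2 <- unname(1 - sel$press[fit$A] / press0)
  }
  fit$x_stats <- sx[c("center", "scale", "dropped")]
  fit$y_stats <- sy[c("center", "scale", "dropped")]
  class(fit) <- c("pls_model", class(fit))
  fit
}
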