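#' Cook's distances for a simple linear regression
#'
#' For the regression of a kinetic response on a taxon's sequence
#' proportion, \eqn{y = \beta_0 + \beta_1 x + e}, the influence of
#' observation \eqn{i} is
#' \deqn{D_i = \frac{e_i^2}{p\,s^2} \cdot \frac{h_{ii}}{(1 - h_{ii})^2}}
#' with \eqn{p = 2} parameters, \eqn{s^2 = RSS/(n - 2)} and leverage
#' \eqn{h_{ii} = 1/n + (x_i - \bar x)^2 / \sum_j (x_j - \bar x)^2}.
#' This equals the leave-one-out definition
#' \eqn{D_i = \sum_j (\hat y_j - \hat y_j^{(i)})^2 / (p s^2)}.
#'
#' @param x predictor (taxon proportion per sample), not all equal.
#' @param y response, same length, length >= 4.
#' @return numeric vector of per-observation distances.
#' @export
#' @examples
#' cooks_distances(c(1, 2, 3, 4), c(1, 2, 3, 10))
cooks_distances <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop_rf("x and y must have equal length")
  if (n < 4L) stop_rf("need at least 4 observations")
  sxx <- sum((x - mean(x))^2)
  if (sxx <= 0) stop_rf("constant predictor: leverage undefined")
  h <- 1 / n + (x - mean(x))^2 / sxx
  beta1 <- sum((x - mean(x)) * (y - mean(y))) / sxx
  beta0 <- mean(y) - beta1 * mean(x)
  e <- y - (beta0 + beta1 * x)
  s2 <- sum(e^2) / (n - 2)
  if (s2 == 0) return(numeric(n))  # perfect fit: nothing is influential
  d <- e^2 / (2 * s2) * h / (1 - h)^2
  # an observation with leverage 1 (e.g. the only sample where a rare
  # taxon occurs) determines the slope by itself: the leave-one-out refit
  # is rank-deficient and the influence is unbounded, but the algebraic
  # form degenerates to 0 * Inf; report Inf explicitly
  d[1 - h < 1e-8] <- Inf
  d
}

#' Censor taxa by Cook's influence distance
#'
#' Regresses the chosen kinetic response (by default the NDF digestion
#' rate) on each taxon's sequence proportion and removes taxa whose
#' maximum Cook's distance exceeds the F quantile
#' \eqn{F(df_1, df_2; 1 - \alpha)}. All taxa are tested against the same
#' original response, so removal is order-independent. Two threshold
#' modes are available: the adaptive default `df = c(2, n - 2)` and a
#' fixed pair (e.g. `c(2, 28)`) reproducing a study-specific criterion
#' regardless of the current sample count. Taxa with identical
#' proportions in all samples cannot enter the regression; they are
#' skipped and noted, never removed.
#'
#' @param table a [taxon_table()] (proportions) or a `clade_matrix`.
#' @param response numeric response named by sample id, or aligned with
#'   the table rows.
#' @param alpha significance level of the F threshold (in (0, 1)).
#' @param df `NULL` for adaptive `(2, n - 2)` or a length-2 numeric pair.
#' @param renormalize re-close rows to 1 after censoring (default
#'   `FALSE`: removed mass is simply dropped).
#' @return list with `table` (censored, same class as input) and
#'   `report` (an `influence_report`: data.frame of per-taxon max Cook's
#'   D, the sample attaining it, and flags, with the threshold and df in
#'   attributes).
#' @export
filter_taxa <- function(table, response, alpha = 0.05, df = NULL,
                        renormalize = FALSE) {
  is_tt <- inherits(table, "taxon_table")
  vals <- if (is_tt) table$values else unclass(table)
  if (!is.matrix(vals)) stop_rf("table must be a taxon_table or matrix")
  n <- nrow(vals)
  if (!is.null(names(response))) {
    if (!all(rownames(vals) %in% names(response)))
      stop_rf("response is missing sample(s): ",
              paste(setdiff(rownames(vals), names(response)), collapse = ", "))
    response <- response[rownames(vals)]
  } else if (length(response) != n) {
    stop_rf("response length does not match the number of samples")
  }
  if (anyNA(response)) stop_rf("response contains missing values")
  if (!(alpha > 0 && alpha < 1)) stop_rf("alpha must be in (0, 1)")
  if (is.null(df)) df <- c(2, n - 2)
  if (length(df) != 2L || any(df <= 0)) stop_rf("df must be two positive values")
  threshold <- qf(1 - alpha, df[1], df[2])

  p <- ncol(vals)
  max_d <- rep(NA_real_, p)
  at_sample <- rep(NA_character_, p)
  skipped <- logical(p)
  for (j in seq_len(p)) {
    xj <- vals[, j]
    if (max(xj) - min(xj) <= 0) { skipped[j] <- TRUE; next }
    dj <- cooks_distances(xj, response)
    i <- which.max(dj)
    max_d[j] <- dj[i]
    at_sample[j] <- rownames(vals)[i]
  }
  removed <- !skipped & !is.na(max_d) & max_d > threshold

  report <- data.frame(taxon_id = colnames(vals), max_cooks_d = max_d,
                       flagged_sample = at_sample, skipped_constant = skipped,
                       removed = removed, row.names = NULL,
                       stringsAsFactors = FALSE)
  attr(report, "threshold") <- threshold
  attr(report, "df") <- df
  attr(report, "alpha") <- alpha
  attr(report, "n") <- n
  class(report) <- c("influence_report", class(report))

  kept <- vals[, !removed, drop = FALSE]
  if (renormalize) {
    rs <- rowSums(kept)
    if (any(rs <= 0)) stop_rf("renormalisation impossible: empty sample row")
    kept <- kept / rs
  }
  out <- if (is_tt) {
    # censored rows no longer close to 1 unless renormalize = TRUE, so the
    # object is assembled directly rather than through the validating
    # constructor; the censored flag records this
    tt <- structure(list(values = kept, lineage = table$lineage[!removed],
                         mode = table$mode, levels = table$levels,
                         metadata = table$metadata),
                    class = "taxon_table")
    attr(tt, "censored") <- TRUE
    attr(tt, "renormalized") <- renormalize
    tt
  } else {
    structure(kept, level = attr(table, "level"),
              lineage = attr(table, "lineage")[!removed],
              class = class(table))
  }
  list(table = out, report = report)
}

#' @export
print.influence_report <- function(x, ...) {
  cat(sprintf(
    "<influence_report> %d taxa tested, %d removed, %d skipped (constant)\n",
    nrow(x), sum(x$removed), sum(x$skipped_constant)))
  cat(sprintf("  threshold F(%g, %g; %g) = %.4f on n = %d samples\n",
              attr(x, "df")[1], attr(x, "df")[2], 1 - attr(x, "alpha"),
              attr(x, "threshold"), attr(x, "n")))
  NextMethod()
}
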