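#' Shannon diversity (natural log)
#'
#' \eqn{H = -\sum_{p_i > 0} p_i \ln p_i} over a proportion vector.
#' Reported in nats; typical amplicon surveys of the rumen give values in
#' the 6--7 range on thousands of taxa, consistent with the natural-log
#' convention used here.
#'
#' @param p nonnegative abundances; renormalised to sum 1 (error if the
#'   sum deviates from 1 by more than `tol` and `p` is not a count/raw
#'   intensity vector — pass counts freely, they are normalised).
#' @param tol tolerance on the proportion sum before renormalising
#'   silently.
#' @return diversity in nats.
#' @export
#' @examples
#' shannon(rep(1 / 80, 80))      # log(80)
#' shannon(c(0.5, 0.25, 0.25))   # 1.0397
shannon <- function(p, tol = 1e-6) {
  if (any(p < 0) || anyNA(p)) stop_rf("proportions must be nonnegative")
  s <- sum(p)
  if (s <= 0) stop_rf("all-zero abundance vector")
  p <- p / s
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Chao1 richness estimator
#'
#' \eqn{S_{chao1} = S_{obs} + F_1^2 / (2 F_2)} where \eqn{F_1} and
#' \eqn{F_2} are the singleton and doubleton counts; when no doubletons
#' are observed the bias-corrected form
#' \eqn{S_{obs} + F_1 (F_1 - 1) / (2 (F_2 + 1))} is used. Requires
#' integer counts: frequency-of-frequency statistics are undefined on
#' proportions.
#'
#' @param counts nonnegative integer vector of per-taxon sequence counts.
#' @return estimated total richness (`>= S_obs` always).
#' @export
#' @examples
#' chao1(c(5, 5, 1, 1, 2))  # S_obs 5, F1 2, F2 1 -> 7
chao1 <- function(counts) {
  if (anyNA(counts) || any(counts < 0)) stop_rf("counts must be nonnegative")
  if (any(counts != round(counts)))
    stop_rf("Chao1 requires integer counts, not proportions")
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (f2 > 0) s_obs + f1^2 / (2 * f2)
  else s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Good's coverage
#'
#' \eqn{1 - F_1 / N}: the estimated probability that one more sequence
#' read would belong to an already-observed taxon.
#'
#' @param counts nonnegative integer vector of per-taxon sequence counts.
#' @return coverage fraction in `[0, 1]`.
#' @export
#' @examples
#' goods_coverage(c(90, rep(1, 10)))  # 0.90
goods_coverage <- function(counts) {
  if (anyNA(counts) || any(counts < 0)) stop_rf("counts must be nonnegative")
  if (any(counts != round(counts)))
    stop_rf("coverage requires integer counts")
  n <- sum(counts)
  if (n <= 0) stop_rf("empty sample")
  1 - sum(counts == 1) / n
}

#' Per-sample diversity summary of a counts table
#'
#' @param counts_table a [taxon_table()] in counts mode.
#' @return data.frame with one row per sample: observed richness, Chao1,
#'   Shannon (nats) and Good's coverage.
#' @export
diversity_summary <- function(counts_table) {
  stopifnot(inherits(counts_table, "taxon_table"))
  if (counts_table$mode != "counts")
    stop_rf("diversity estimators need counts; proportion tables cannot ",
            "yield Chao1 or coverage")
  v <- counts_table$values
  data.frame(
    sample_id = rownames(v),
    s_obs = apply(v, 1L, function(x) sum(x > 0)),
    chao1 = apply(v, 1L, chao1),
    shannon = apply(v, 1L, shannon),
    coverage = apply(v, 1L, goods_coverage),
    row.names = NULL, stringsAsFactors = FALSE)
}
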