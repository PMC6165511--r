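#' Compare clade levels by simultaneously predicting all responses
#'
#' Fits one multi-response (PLS2) model per clade level — all six
#' digestion responses predicted at once from the clade's proportion
#' matrix — with the latent-vector count chosen by leave-one-out PRESS,
#' and reports the percent of response variation explained and the
#' selected count per level. The level attaining the maximum identifies
#' the taxonomic resolution that best predicts fiber digestion.
#'
#' @param tables named list of samples x clades matrices (e.g. from
#'   [aggregate_clade()] at several levels), all with identical row order.
#' @param Y units x responses matrix aligned with the tables' rows.
#' @param A_max latent-vector candidate cap.
#' @return data.frame with columns `level`, `pct_explained`
#'   (training R2Y x 100), `q2` (cross-validated), `latent_vectors`;
#'   attribute `best` names the argmax level.
#' @export
clade_comparison <- function(tables, Y, A_max = 5L) {
  if (!length(tables)) stop_rf("no clade tables given")
  if (is.null(names(tables))) stop_rf("tables must be named by level")
  Y <- as.matrix(Y)
  rows <- lapply(names(tables), function(lv) {
    M <- unclass(tables[[lv]])
    if (nrow(M) != nrow(Y)) {
      warning("level ", lv, " skipped: sample mismatch", call. = FALSE)
      return(NULL)
    }
    fit <- pls_regression(M, Y, A_max = A_max)
    data.frame(level = lv, pct_explained = 100 * fit$r2y_cum[fit$A],
               q2 = fit$q2, latent_vectors = fit$A,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "best") <- out$level[which.max(out$pct_explained)]
  out
}

#' Per-genus association report for one kinetic response
#'
#' Single-response (PLS1) regression of a fiber digestion parameter on
#' censored genus proportions, with LOO-selected latent vectors. Each
#' genus gets a VIP score and the sign of its standardized regression
#' coefficient; genera with VIP > 0.8 are flagged important, and the
#' signed percentile lists hold, for each sign, the top
#' `ceiling(0.05 p)` genera by VIP (ties broken by coefficient
#' magnitude) — the "95th percentile" associations.
#'
#' @param X samples x genera proportion matrix (censored).
#' @param y numeric response aligned with rows of `X`.
#' @param vip_cutoff importance threshold (default 0.8).
#' @param list_fraction fraction of genera per signed percentile list.
#' @param A_max latent-vector candidate cap.
#' @return an `association_report`: data.frame with one row per genus
#'   (`genus`, `vip`, `coef`, `sign`, `important`, `percentile_list`),
#'   attributes `pct_explained`, `q2`, `A`, and the model in
#'   `attr(, "model")`.
#' @export
genus_associations <- function(X, y, vip_cutoff = 0.8,
                               list_fraction = 0.05, A_max = 5L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stop_rf("response length must match rows of X")
  fit <- pls_regression(X, y, A_max = A_max)
  v <- fit$vip
  b <- drop(fit$coefficients)
  genera <- names(v)
  p <- length(genera)
  n_list <- ceiling(list_fraction * p)
  if (p < 20)
    message("only ", p, " genera: percentile lists may be empty or tiny")

  pick <- function(side) {
    idx <- if (side > 0) which(b > 0) else which(b < 0)
    if (!length(idx)) return(character(0))
    idx <- idx[order(-v[idx], -abs(b[idx]))]
    genera[idx[seq_len(min(n_list, length(idx)))]]
  }
  pos <- pick(+1); neg <- pick(-1)

  plist <- rep("none", p)
  plist[genera %in% pos] <- "positive"
  plist[genera %in% neg] <- "negative"

  rep_df <- data.frame(genus = genera, vip = unname(v), coef = unname(b),
                       sign = ifelse(b >= 0, "+", "-"),
                       important = unname(v) > vip_cutoff,
                       percentile_list = plist,
                       stringsAsFactors = FALSE)
  rep_df <- rep_df[order(-rep_df$vip), ]
  rownames(rep_df) <- NULL
  attr(rep_df, "pct_explained") <- 100 * fit$r2y_cum[fit$A]
  attr(rep_df, "q2") <- fit$q2
  attr(rep_df, "A") <- fit$A
  attr(rep_df, "model") <- fit
  class(rep_df) <- c("association_report", class(rep_df))
  rep_df
}

#' @export
print.association_report <- function(x, ...) {
  cat(sprintf(
    "<association_report> %d genera, %d important (VIP > 0.8), %.1f%% response explained (A = %d)\n",
    nrow(x), sum(x$important), attr(x, "pct_explained"), attr(x, "A")))
  cat("  positive: ", paste(x$genus[x$percentile_list == "positive"],
                            collapse = ", "), "\n")
  cat("  negative: ", paste(x$genus[x$percentile_list == "negative"],
                            collapse = ", "), "\n")
  invisible(x)
}
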