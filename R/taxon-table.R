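#' Taxon-by-sample abundance table with lineage strings
#'
#' The central community container: a samples x taxa numeric matrix plus a
#' semicolon-delimited lineage per taxon (phylum first, at most 7 levels,
#' mirroring classification by shared branching points). Values are either
#' relative proportions of 16S rRNA gene sequences (`mode = "proportions"`,
#' rows summing to 1) or integer sequence counts (`mode = "counts"`).
#'
#' @param values numeric matrix, samples in rows, taxa in columns; both
#'   dimnames required (sample ids, taxon ids).
#' @param lineage character vector of lineage strings, one per taxon.
#' @param mode `"proportions"` or `"counts"`.
#' @param levels optional level names (phylum ... species); defaults to the
#'   canonical ranks truncated to the lineage depth.
#' @param metadata optional per-sample data.frame keyed by `sample_id`.
#' @return object of class `taxon_table`.
#' @export
taxon_table <- function(values, lineage, mode = c("proportions", "counts"),
                        levels = NULL, metadata = NULL) {
  mode <- match.arg(mode)
  if (!is.matrix(values) || !is.numeric(values))
    stop_rf("values must be a numeric matrix (samples x taxa)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_rf("values must carry sample and taxon dimnames")
  if (anyDuplicated(colnames(values)))
    stop_rf("duplicate taxon ids")
  if (anyDuplicated(rownames(values)))
    stop_rf("duplicate sample ids")
  if (length(lineage) != ncol(values))
    stop_rf("one lineage string per taxon required")
  if (any(!nzchar(lineage)) || anyNA(lineage))
    stop_rf("malformed lineage: empty or missing string")
  if (any(values < 0)) stop_rf("negative abundance values")
  parts <- strsplit(lineage, ";", fixed = TRUE)
  depth <- lengths(parts)
  if (any(vapply(parts, function(p) any(!nzchar(p)), logical(1))))
    stop_rf("malformed lineage: empty level label")
  if (max(depth) > 7L)
    stop_rf("lineage deeper than 7 levels")
  canonical <- c("phylum", "class", "order", "family", "genus", "species",
                 "strain")
  levels <- levels %||% canonical[seq_len(max(depth))]
  if (length(levels) < max(depth))
    stop_rf("levels shorter than lineage depth")
  if (mode == "proportions") {
    rs <- rowSums(values)
    if (any(abs(rs - 1) > 1e-6))
      stop_rf("proportion rows must sum to 1 within 1e-6")
  } else {
    if (any(values != round(values)))
      stop_rf("counts mode requires integer values")
  }
  structure(list(values = values, lineage = lineage, mode = mode,
                 levels = levels, metadata = metadata),
            class = "taxon_table")
}

#' @export
print.taxon_table <- function(x, ...) {
  cat(sprintf("<taxon_table> %d samples x %d taxa (%s), levels: %s\n",
              nrow(x$values), ncol(x$values), x$mode,
              paste(x$levels, collapse = " > ")))
  invisible(x)
}

#' @export
dim.taxon_table <- function(x) dim(x$values)

#' Convert a counts table to proportions
#'
#' @param table a `taxon_table` in counts mode.
#' @return the same table with rows normalised to 1 and
#'   `mode = "proportions"`; the original mode is recorded in
#'   `attr(, "source_mode")`.
#' @export
as_proportions <- function(table) {
  stopifnot(inherits(table, "taxon_table"))
  if (table$mode == "proportions") return(table)
  rs <- rowSums(table$values)
  if (any(rs == 0)) stop_rf("cannot normalise a sample with zero total count")
  out <- taxon_table(table$values / rs, table$lineage, "proportions",
                     levels = table$levels, metadata = table$metadata)
  attr(out, "source_mode") <- "counts"
  out
}

#' Read a taxon table from TSV
#'
#' Expects the exchange dialect written by [write_dataset()]: first column
#' `taxon_id`, second `lineage` (semicolon-delimited, phylum first), the
#' remaining columns one per sample. Count tables (all values integer and
#' any value > 1) are auto-normalised to proportions with the source mode
#' recorded.
#'
#' @param path TSV file path.
#' @param normalize auto-convert counts to proportions (default `TRUE`).
#' @return a [taxon_table()].
#' @export
read_taxon_table <- function(path, normalize = TRUE) {
  if (!file.exists(path)) stop_rf("no such file: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = 1:2))
  if (ncol(dt) < 3L || !identical(names(dt)[1:2], c("taxon_id", "lineage")))
    stop_rf("expected columns taxon_id, lineage, then sample columns")
  if (anyDuplicated(dt$taxon_id))
    stop_rf("duplicate taxon ids in ", path)
  m <- t(as.matrix(as.data.frame(dt)[, -(1:2), drop = FALSE]))
  colnames(m) <- dt$taxon_id
  if (!is.numeric(m)) stop_rf("non-numeric abundance values in ", path)
  is_counts <- all(m == round(m)) && any(m > 1)
  tab <- taxon_table(m, dt$lineage,
                     mode = if (is_counts) "counts" else "proportions")
  if (is_counts && normalize) tab <- as_proportions(tab)
  tab
}

#' Aggregate a taxon table at a clade level
#'
#' Sums proportions (or counts) over all taxa that share the lineage
#' prefix down to `level`. Row totals are conserved exactly, so per-sample
#' mass is preserved at every level. Column order is lexicographic in the
#' clade's full prefix, hence deterministic.
#'
#' @param table a [taxon_table()].
#' @param level level label (e.g. `"phylum"`, `"genus"`) or 1-based depth.
#' @return a `clade_matrix`: samples x clades matrix with attributes
#'   `level` and `lineage` (the clade prefixes).
#' @export
#' @examples
#' cfg <- sim_config(seed = 42)
#' com <- simulate_community(cfg)
#' ph <- aggregate_clade(com$table, "phylum")
#' ncol(ph)
aggregate_clade <- function(table, level) {
  stopifnot(inherits(table, "taxon_table"))
  if (is.character(level)) {
    idx <- match(level, table$levels)
    if (is.na(idx)) stop_rf("unknown level label: ", level)
  } else {
    idx <- as.integer(level)
  }
  parts <- strsplit(table$lineage, ";", fixed = TRUE)
  if (idx < 1L || idx > max(lengths(parts)))
    stop_rf("level outside available lineage depth")
  prefix <- vapply(parts, function(p) {
    # taxa classified less deeply than `level` keep an explicit
    # unclassified placeholder named after the lowest assigned parent
    if (length(p) >= idx) paste(p[seq_len(idx)], collapse = ";")
    else paste(c(p, sprintf("unclassified_%s", p[length(p)])), collapse = ";")
  }, character(1))
  groups <- sort(unique(prefix))
  out <- matrix(0, nrow(table$values), length(groups),
                dimnames = list(rownames(table$values),
                                vapply(strsplit(groups, ";", fixed = TRUE),
                                       function(p) p[length(p)], character(1))))
  for (j in seq_along(groups))
    out[, j] <- rowSums(table$values[, prefix == groups[j], drop = FALSE])
  structure(out, level = if (is.character(level)) level else
              table$levels[idx], lineage = groups,
            class = c("clade_matrix", class(out)))
}
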