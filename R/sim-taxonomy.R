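#' Generate a nested lineage set
#'
#' Builds a proper taxonomy tree with the clade counts in `config`:
#' every genus gets one semicolon-delimited lineage string, phylum first,
#' and every clade at a lower level nests inside exactly one parent, so
#' aggregation at any level is well defined.
#'
#' @param config a [sim_config()].
#' @return data.frame with columns `taxon_id` and `lineage` (one row per
#'   genus), plus attribute `levels` naming the lineage levels.
#' @export
#' @examples
#' tx <- make_taxonomy(sim_config(clade_counts = c(phylum = 2, genus = 4)))
#' tx$lineage
make_taxonomy <- function(config) {
  if (!inherits(config, "sim_config")) stop_rf("config must be a sim_config")
  counts <- config$clade_counts
  levels <- names(counts)
  n_levels <- length(counts)
  set.seed(child_seed(config$seed, 1L))

  # parent assignment per level: clade k at level l gets a parent at level
  # l-1; the first `n_parent` children go one to each parent so every
  # parent has at least one descendant, the rest are assigned at random.
  parent_of <- vector("list", n_levels)
  parent_of[[1L]] <- rep(NA_integer_, counts[1L])
  for (l in seq_len(n_levels)[-1L]) {
    n_par <- counts[l - 1L]
    n_child <- counts[l]
    if (n_child < n_par)
      stop_rf("clade_counts must be non-decreasing (level ", levels[l], ")")
    extra <- n_child - n_par
    parent_of[[l]] <- c(seq_len(n_par),
                        if (extra > 0) sample.int(n_par, extra, replace = TRUE))
  }

  label <- function(level, k) sprintf("%s_%02d", level, k)
  lineage_at <- vector("list", n_levels)
  lineage_at[[1L]] <- vapply(seq_len(counts[1L]),
                             function(k) label(levels[1L], k), character(1))
  for (l in seq_len(n_levels)[-1L]) {
    lineage_at[[l]] <- vapply(seq_len(counts[l]), function(k) {
      paste(lineage_at[[l - 1L]][parent_of[[l]][k]], label(levels[l], k),
            sep = ";")
    }, character(1))
  }

  out <- data.frame(
    taxon_id = sprintf("g%03d", seq_len(counts[n_levels])),
    lineage = lineage_at[[n_levels]],
    stringsAsFactors = FALSE
  )
  attr(out, "levels") <- levels
  out
}
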