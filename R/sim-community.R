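#' Simulate a rumen bacterial community table
#'
#' Draws genus-level relative abundances for every sample of the crossover
#' design. Genus intensities are log-normal around genus-specific baseline
#' means (heavy-tailed, as in real 16S tables) and closed to proportions;
#' the first two phyla are dominant, jointly carrying
#' `config$dominant_share` of the expected mass, mimicking the
#' Bacteroidetes + Firmicutes share of the mammalian gut. A configurable
#' number of rare taxa is appended, each present in exactly
#' `rare_prevalence` samples with a large spike so that it exerts extreme
#' leverage on abundance--response regressions. Integer counts are drawn
#' from a multinomial at `reads_per_sample` depth for the diversity
#' estimators.
#'
#' @param config a [sim_config()].
#' @param taxonomy optional output of [make_taxonomy()]; generated from
#'   `config` if missing.
#' @return list with elements
#'   \describe{
#'     \item{table}{[taxon_table()] of proportions (samples x taxa).}
#'     \item{counts}{[taxon_table()] of multinomial counts at the same
#'       expected composition.}
#'     \item{truth}{`ground_truth` list: `planted_genus_ids`, `gamma`
#'       (named per-genus true effects, zero for unplanted genera), and
#'       `rare_taxon_ids`.}
#'   }
#' @export
simulate_community <- function(config, taxonomy = NULL) {
  if (!inherits(config, "sim_config")) stop_rf("config must be a sim_config")
  taxonomy <- taxonomy %||% make_taxonomy(config)
  samples <- design_samples(config)
  n_s <- nrow(samples)
  n_g <- nrow(taxonomy)
  if (config$n_rare_taxa > 0 && config$rare_prevalence > n_s)
    stop_rf("rare_prevalence exceeds the number of samples (", n_s, ")")

  set.seed(child_seed(config$seed, 2L))

  phylum <- vapply(strsplit(taxonomy$lineage, ";", fixed = TRUE), `[`,
                   character(1), 1L)
  phyla <- unique(phylum)
  dominant <- phyla[seq_len(min(2L, length(phyla)))]
  in_dom <- phylum %in% dominant

  # baseline genus means: power-law-ish spread within each block, scaled so
  # the dominant phyla carry the configured expected share
  base <- rlnorm(n_g, meanlog = 0, sdlog = 1.2)
  w_dom <- if (any(in_dom)) config$dominant_share / sum(base[in_dom]) else 0
  w_rest <- if (any(!in_dom)) (1 - config$dominant_share) / sum(base[!in_dom]) else 0
  mu <- base * ifelse(in_dom, w_dom, w_rest)

  # per-sample log-normal perturbation, closed to proportions
  eps <- matrix(rnorm(n_s * n_g, 0, config$abundance_sdlog), n_s, n_g)
  intensity <- sweep(exp(eps), 2L, mu, `*`)

  # planted genera: chosen among the dominant phyla so their abundance is
  # not vanishingly small relative to noise
  planted_pool <- which(in_dom)
  if (length(planted_pool) < config$n_planted) planted_pool <- seq_len(n_g)
  planted <- sort(sample(planted_pool, config$n_planted))
  gamma <- setNames(numeric(n_g), taxonomy$taxon_id)
  gamma[planted] <- config$gamma

  taxon_ids <- taxonomy$taxon_id
  lineage <- taxonomy$lineage

  # rare taxa: spike in a few samples only, zero elsewhere
  rare_ids <- character(0)
  if (config$n_rare_taxa > 0) {
    rare_ids <- sprintf("rare%02d", seq_len(config$n_rare_taxa))
    rare_phy <- sample(phyla, config$n_rare_taxa, replace = TRUE)
    rare_lineage <- sprintf("%s;%s", rare_phy,
                            paste(vapply(seq_len(config$n_rare_taxa), function(i)
                              paste(sprintf("rare_%s_%02d",
                                            names(config$clade_counts)[-1], i),
                                    collapse = ";"), character(1))))
    spike <- matrix(0, n_s, config$n_rare_taxa)
    for (j in seq_len(config$n_rare_taxa)) {
      occ <- sample.int(n_s, config$rare_prevalence)
      # spike comparable to a dominant genus: extreme single-sample leverage
      spike[occ, j] <- quantile(intensity, 0.99)
    }
    intensity <- cbind(intensity, spike)
    taxon_ids <- c(taxon_ids, rare_ids)
    lineage <- c(lineage, rare_lineage)
    gamma <- c(gamma, setNames(numeric(config$n_rare_taxa), rare_ids))
  }

  props <- intensity / rowSums(intensity)
  dimnames(props) <- list(samples$sample_id, taxon_ids)

  counts <- t(vapply(seq_len(n_s), function(i)
    rmultinom(1L, config$reads_per_sample, props[i, ])[, 1L],
    integer(ncol(props))))
  dimnames(counts) <- dimnames(props)

  truth <- structure(list(planted_genus_ids = taxonomy$taxon_id[planted],
                          gamma = gamma,
                          rare_taxon_ids = rare_ids,
                          dominant_phyla = dominant),
                     class = "ground_truth")

  list(table = taxon_table(props, lineage, "proportions",
                           levels = names(config$clade_counts),
                           metadata = samples),
       counts = taxon_table(counts, lineage, "counts",
                            levels = names(config$clade_counts),
                            metadata = samples),
       truth = truth)
}
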