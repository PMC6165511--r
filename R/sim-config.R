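#' Simulation configuration for a crossover in-situ digestion study
#'
#' Builds the configuration object consumed by [make_taxonomy()],
#' [simulate_community()] and [simulate_kinetics()]. Defaults emulate a
#' two-season, two-diet crossover trial with eight ruminally cannulated
#' animals, two in-situ substrates incubated at 24--120 h, and a rumen
#' bacterial community of 80 genera nested in 10 phyla, two of which
#' dominate (jointly ~90 % of sequences). A small set of "planted" genera
#' carries a true effect on the fractional digestion rate so that feature
#' recovery by the association stage can be tested.
#'
#' @param n_animals number of animals (each sampled in every season x diet
#'   cell of the crossover).
#' @param seasons,diets,substrates character vectors of design labels.
#' @param times_h in-situ bag removal times in hours, strictly increasing.
#' @param clade_counts named integer vector giving the number of clades at
#'   each lineage level, phylum first, genus (or the lowest level) last.
#'   Must be non-decreasing.
#' @param n_planted number of genera with a non-zero true effect.
#' @param effect_size per-planted-genus slope on the fractional rate c
#'   (h^-1 per standard-deviation of log abundance); recycled to
#'   `n_planted`. Signs alternate (+, -, +, ...) so both association
#'   directions occur.
#' @param base_params named list keyed by substrate, each a numeric vector
#'   `c(a, b, c)`: rapidly disappearing intercept (%), slowly digestible
#'   pool (%) and fractional rate (h^-1). Defaults use a medium-quality
#'   (hay-like) substrate with slower rate but larger extent and a
#'   low-quality (straw-like) substrate with faster rate but smaller
#'   extent, matching in-situ values typical for forage fiber.
#' @param fraction_scale named multipliers on the base rate for the three
#'   fiber fractions (NDF, cellulose, hemicellulose).
#' @param obs_noise_sd Gaussian observation noise on percent digested.
#' @param dominant_share expected joint share of the two dominant phyla.
#' @param abundance_sdlog log-scale dispersion of genus intensities (heavy
#'   tails exercise the influence filter).
#' @param n_rare_taxa number of extra rare taxa appended to the table.
#' @param rare_prevalence number of samples each rare taxon occupies.
#' @param reads_per_sample sequencing depth used to draw integer counts.
#' @param c_floor lower floor applied to any generated fractional rate.
#' @param drop_animal_fall if `TRUE`, the last animal is removed from the
#'   fall season (unbalanced design as happens in real trials); default
#'   keeps the design balanced.
#' @param seed integer master seed; identical configurations (including
#'   seed) generate bit-identical datasets.
#'
#' @return an object of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$n_genera
sim_config <- function(n_animals = 8L,
                       seasons = c("spring", "fall"),
                       diets = c("hay", "straw"),
                       substrates = c("hay", "straw"),
                       times_h = c(24, 36, 48, 72, 96, 120),
                       clade_counts = c(phylum = 10L, class = 16L,
                                        order = 26L, family = 45L,
                                        genus = 80L),
                       n_planted = 3L,
                       effect_size = 0.005,
                       base_params = list(hay = c(a = 8, b = 62, c = 0.017),
                                          straw = c(a = 5, b = 52, c = 0.022)),
                       fraction_scale = c(NDF = 1, cellulose = 0.9,
                                          hemicellulose = 1.1),
                       obs_noise_sd = 2,
                       dominant_share = 0.9,
                       abundance_sdlog = 1,
                       n_rare_taxa = 3L,
                       rare_prevalence = 1L,
                       reads_per_sample = 30000L,
                       c_floor = 1e-4,
                       drop_animal_fall = FALSE,
                       seed = 20090401L) {
  if (!is.numeric(n_animals) || n_animals < 1)
    stop_rf("n_animals must be >= 1")
  for (nm in c("seasons", "diets", "substrates")) {
    v <- get(nm)
    if (!is.character(v) || length(v) < 1L || anyDuplicated(v))
      stop_rf(nm, " must be distinct non-empty labels")
  }
  if (length(times_h) < 3L || any(times_h <= 0) || is.unsorted(times_h, strictly = TRUE))
    stop_rf("times_h must be >= 3 strictly increasing positive hours")
  if (any(clade_counts < 1L))
    stop_rf("clade counts must all be >= 1")
  if (is.null(names(clade_counts)) || anyNA(names(clade_counts)))
    stop_rf("clade_counts must be named by lineage level")
  if (is.unsorted(clade_counts))
    stop_rf("clade_counts must be non-decreasing from phylum down")
  n_genera <- as.integer(clade_counts[length(clade_counts)])
  if (n_planted < 0 || n_planted > n_genera)
    stop_rf("n_planted must be between 0 and the number of genera")
  assert_scalar_number(obs_noise_sd, "obs_noise_sd", lower = 0)
  assert_scalar_number(dominant_share, "dominant_share", lower = 0, upper = 1)
  assert_scalar_number(abundance_sdlog, "abundance_sdlog", lower = 0)
  if (n_rare_taxa < 0) stop_rf("n_rare_taxa must be >= 0")
  if (n_rare_taxa > 0 && rare_prevalence < 1L)
    stop_rf("rare_prevalence must be >= 1")
  if (!all(substrates %in% names(base_params)))
    stop_rf("base_params must have an entry for every substrate")
  for (s in substrates) {
    bp <- base_params[[s]]
    if (length(bp) != 3L || any(bp[1:2] < 0) || bp[3] < 0)
      stop_rf("base_params[['", s, "']] must be c(a, b, c) with a, b, c >= 0")
  }
  gamma <- rep_len(abs(effect_size), n_planted)
  if (n_planted > 0)
    gamma <- gamma * rep_len(c(1, -1), n_planted)

  structure(list(
    n_animals = as.integer(n_animals),
    seasons = seasons, diets = diets, substrates = substrates,
    times_h = as.numeric(times_h),
    clade_counts = setNames(as.integer(clade_counts), names(clade_counts)),
    n_genera = n_genera,
    n_planted = as.integer(n_planted),
    gamma = gamma,
    base_params = base_params,
    fraction_scale = fraction_scale,
    obs_noise_sd = obs_noise_sd,
    dominant_share = dominant_share,
    abundance_sdlog = abundance_sdlog,
    n_rare_taxa = as.integer(n_rare_taxa),
    rare_prevalence = as.integer(rare_prevalence),
    reads_per_sample = as.integer(reads_per_sample),
    c_floor = c_floor,
    drop_animal_fall = isTRUE(drop_animal_fall),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  design : %d animals x {%s} x {%s}, substrates {%s}\n",
              x$n_animals, paste(x$seasons, collapse = ","),
              paste(x$diets, collapse = ","),
              paste(x$substrates, collapse = ",")))
  cat(sprintf("  times  : %s h\n", paste(x$times_h, collapse = ", ")))
  cat(sprintf("  taxa   : %s\n",
              paste(sprintf("%d %s", x$clade_counts, names(x$clade_counts)),
                    collapse = ", ")))
  cat(sprintf("  planted: %d genera, gamma = %s\n", x$n_planted,
              paste(signif(x$gamma, 3), collapse = ", ")))
  cat(sprintf("  noise  : sd(D) = %g %%; seed = %d\n", x$obs_noise_sd, x$seed))
  invisible(x)
}

#' Design samples implied by a configuration
#'
#' One sample per animal x season x diet cell (the unit at which the rumen
#' is sampled); substrate enters only the kinetics design.
#' @noRd
design_samples <- function(config) {
  g <- expand.grid(animal = paste0("A", seq_len(config$n_animals)),
                   season = config$seasons, diet = config$diets,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (config$drop_animal_fall) {
    drop <- g$season == "fall" & g$animal == paste0("A", config$n_animals)
    g <- g[!drop, , drop = FALSE]
  }
  g$sample_id <- sprintf("%s_%s_%s", g$animal, g$season, g$diet)
  rownames(g) <- NULL
  g
}
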