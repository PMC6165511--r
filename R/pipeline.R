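#' Run the full analysis pipeline on a synthetic dataset
#'
#' Orchestrates simulate -> fit kinetics -> marker digestibility ->
#' diversity -> influence filter -> PLS association into one reproducible
#' run directory. Every stage writes CSV; a JSON manifest records the
#' seed, the configuration and a content hash so two runs with the same
#' configuration are numerically identical.
#'
#' @param config a [sim_config()], or a path to a JSON file of
#'   `sim_config()` arguments.
#' @param out_dir run directory (created; must not contain a manifest
#'   unless `overwrite`).
#' @param filter_alpha significance level of the Cook's-distance filter.
#' @param filter_df `NULL` for adaptive `(2, n - 2)` df, or a fixed pair.
#' @param filter_response response used for censoring (default the NDF
#'   digestion rate).
#' @param A_max latent-vector cap for all PLS stages.
#' @param overwrite allow writing into an existing run directory.
#' @return invisibly, a list with every stage result and the manifest.
#' @export
run_pipeline <- function(config, out_dir,
                         filter_alpha = 0.05, filter_df = NULL,
                         filter_response = "NDF_rate",
                         A_max = 5L, overwrite = FALSE) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_rf("config file not found: ", config)
    args <- jsonlite::read_json(config, simplifyVector = TRUE)
    if (!is.null(args$clade_counts))
      args$clade_counts <- unlist(args$clade_counts)
    if (!is.null(args$base_params))
      args$base_params <- lapply(args$base_params, unlist)
    config <- do.call(sim_config, args)
  }
  stopifnot(inherits(config, "sim_config"))
  manifest_path <- file.path(out_dir, "run_manifest.json")
  if (file.exists(manifest_path) && !overwrite)
    stop_rf("run directory already holds a manifest (use overwrite = TRUE)")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage_files <- list()
  put <- function(name, df) {
    f <- file.path(out_dir, paste0(name, ".csv"))
    data.table::fwrite(df, f)
    stage_files[[name]] <<- list(file = basename(f), rows = nrow(df))
  }

  # stage 1: simulate
  ds <- simulate_dataset(config)
  write_dataset(ds, file.path(out_dir, "data"), overwrite = overwrite)
  stage_files$data <- list(file = "data/manifest.json",
                           rows = nrow(ds$table$values))

  # stage 2: kinetics fits and the six-response matrix
  fits <- fit_all_kinetics(ds$timecourses)
  fit_df <- do.call(rbind, lapply(fits, function(f)
    data.frame(animal = f$unit$animal, season = f$unit$season,
               diet = f$unit$diet, substrate = f$unit$substrate,
               fraction = f$unit$fraction, a = f$a, b = f$b, c = f$c,
               ext120 = f$ext120, rss = f$rss, converged = f$converged,
               degenerate = f$degenerate, stringsAsFactors = FALSE)))
  put("kinetics_fits", fit_df)
  Y <- summarize_kinetics(fits)
  units_df <- attr(Y, "units")
  rownames(units_df) <- NULL
  put("responses", data.frame(unit = rownames(Y), units_df,
                              as.data.frame(Y, row.names = FALSE),
                              check.names = FALSE))

  # stage 3: lignin-marker digestibility from the bundled compositions
  feed <- data.table::fread(system.file("extdata", "feed_composition.csv",
                                        package = "rumenfiber"),
                            data.table = FALSE)
  feces <- data.table::fread(system.file("extdata",
                                         "synthetic_feces_composition.csv",
                                         package = "rumenfiber"),
                             data.table = FALSE)
  dig <- marker_digestibility_table(feed, feces)
  put("digestibility", dig)

  # stage 4: diversity on counts
  put("diversity", diversity_summary(ds$counts))

  # stage 5: censor genus table against the chosen response, per substrate
  units <- attr(Y, "units")
  genus_level <- ds$table$levels[length(ds$table$levels)]
  filt <- list()
  assoc <- list()
  clade_rows <- list()
  for (sub in config$substrates) {
    in_sub <- units$substrate == sub
    y_sub <- Y[in_sub, , drop = FALSE]
    sample_ids <- sprintf("%s_%s_%s", units$animal[in_sub],
                          units$season[in_sub], units$diet[in_sub])
    gm <- aggregate_clade(ds$table, genus_level)[sample_ids, , drop = FALSE]
    resp <- setNames(y_sub[, filter_response], sample_ids)
    fr <- filter_taxa(gm, resp, alpha = filter_alpha, df = filter_df)
    filt[[sub]] <- fr
    put(paste0("influence_report_", sub),
        cbind(fr$report, substrate = sub))

    # stage 6a: clade comparison (all six responses at once)
    lv_tabs <- lapply(setNames(ds$table$levels, ds$table$levels),
                      function(lv)
                        aggregate_clade(ds$table, lv)[sample_ids, ,
                                                      drop = FALSE])
    cc <- clade_comparison(lv_tabs, y_sub, A_max = A_max)
    cc$substrate <- sub
    clade_rows[[sub]] <- cc

    # stage 6b: per-response genus association lists on the censored table
    for (resp_name in colnames(Y)) {
      ar <- genus_associations(unclass(fr$table), y_sub[, resp_name],
                               A_max = A_max)
      key <- paste0(sub, ".", resp_name)
      assoc[[key]] <- ar
      adf <- as.data.frame(ar)
      rownames(adf) <- NULL
      put(paste0("associations_", sub, "_", resp_name),
          data.frame(adf, pct_explained = attr(ar, "pct_explained"),
                     q2 = attr(ar, "q2"), A = attr(ar, "A")))
    }
  }
  clade_df <- do.call(rbind, clade_rows)
  put("clade_comparison", clade_df)

  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                               digits = NA)
  manifest <- list(seed = config$seed, config = unclass(config),
                   config_hash = fnv1a(as.character(cfg_json)),
                   stages = stage_files)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(dataset = ds, fits = fits, responses = Y,
                 digestibility = dig, filter = filt,
                 clade_comparison = clade_df, associations = assoc,
                 manifest = manifest, out_dir = out_dir))
}

# polynomial rolling hash (mod 2^31 - 1); cheap content fingerprint
fnv1a <- function(s) {
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Lignin-marker digestibility table from composition data
#'
#' Computes nutrient:lignin ratios in forage, supplement and feces and
#' the intake-weighted apparent digestibility per diet and nutrient.
#'
#' @param feed data.frame with columns `feed` (forage names plus
#'   `"supplement"`), nutrient columns (e.g. `NDF`, `ADF`, `N`),
#'   `lignin`, and `dmi_kg_d` (dry-matter intake).
#' @param feces data.frame with columns `diet`, nutrient columns and
#'   `lignin` (composition of feces on the matching diet).
#' @return data.frame: one row per diet x nutrient with diet ratio, feces
#'   ratio and apparent digestibility (kg/kg).
#' @export
marker_digestibility_table <- function(feed, feces) {
  nutrients <- setdiff(intersect(names(feed), names(feces)),
                       c("feed", "diet", "lignin", "dmi_kg_d", "DM"))
  sup <- feed[feed$feed == "supplement", , drop = FALSE]
  out <- list()
  for (d in feces$diet) {
    fo <- feed[feed$feed == d, , drop = FALSE]
    fe <- feces[feces$diet == d, , drop = FALSE]
    if (nrow(fo) != 1L) stop_rf("feed table lacks forage row for diet ", d)
    for (nu in nutrients) {
      r_diet <- diet_ratio(fo[[nu]] / fo$lignin,
                           if (nrow(sup)) sup[[nu]] / sup$lignin else 0,
                           fo$dmi_kg_d,
                           if (nrow(sup)) sup$dmi_kg_d else 0)
      r_feces <- fe[[nu]] / fe$lignin
      dig <- apparent_digestibility(r_feces, r_diet)
      out[[paste(d, nu)]] <- data.frame(
        diet = d, nutrient = nu, diet_ratio = r_diet,
        feces_ratio = r_feces, digestibility = as.numeric(dig),
        negative = attr(dig, "negative"), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarise a completed run directory
#'
#' Reads the CSV outputs of [run_pipeline()] and prints a plain-text
#' report: kinetics summaries by diet x season x substrate, the
#' clade-level percent-explained table, and per-response important-genus
#' counts with the signed percentile lists. Missing stages are reported
#' as absent rather than failing.
#'
#' @param run_dir a directory written by [run_pipeline()].
#' @param file optional path to also write the report text to.
#' @return invisibly, the report lines (character vector).
#' @export
pipeline_report <- function(run_dir, file = NULL) {
  manifest_path <- file.path(run_dir, "run_manifest.json")
  if (!file.exists(manifest_path)) stop_rf("not a run directory: ", run_dir)
  manifest <- jsonlite::read_json(manifest_path)
  lines <- c(sprintf("Pipeline run report  (seed %s, config %s)",
                     manifest$seed, manifest$config_hash), "")
  rd <- function(name) {
    f <- file.path(run_dir, paste0(name, ".csv"))
    if (file.exists(f)) data.table::fread(f, data.table = FALSE) else NULL
  }

  kf <- rd("kinetics_fits")
  if (is.null(kf)) {
    lines <- c(lines, "[kinetics stage absent]")
  } else {
    agg <- stats::aggregate(cbind(c, ext120) ~ diet + season + substrate +
                              fraction, data = kf, FUN = mean)
    lines <- c(lines, "Mean digestion rate (/h) and 120-h extent (%):",
               utils::capture.output(print(agg, row.names = FALSE)), "")
  }

  cc <- rd("clade_comparison")
  if (is.null(cc)) {
    lines <- c(lines, "[clade comparison absent]")
  } else {
    lines <- c(lines, "Variation in the six responses explained by clade level:",
               utils::capture.output(print(cc, row.names = FALSE)), "")
  }

  assoc_files <- list.files(run_dir, pattern = "^associations_.*\\.csv$")
  if (!length(assoc_files)) {
    lines <- c(lines, "[association stage absent]")
  } else {
    lines <- c(lines, "Per-response genus associations:")
    for (f in sort(assoc_files)) {
      a <- data.table::fread(file.path(run_dir, f), data.table = FALSE)
      nm <- sub("^associations_", "", sub("\\.csv$", "", f))
      lines <- c(lines, sprintf(
        "  %-30s important: %2d  explained: %5.1f%%  +[%s]  -[%s]",
        nm, sum(a$important), a$pct_explained[1],
        paste(a$genus[a$percentile_list == "positive"], collapse = ","),
        paste(a$genus[a$percentile_list == "negative"], collapse = ",")))
    }
  }

  dv <- rd("diversity")
  if (!is.null(dv))
    lines <- c(lines, "", sprintf(
      "Diversity: mean S_obs %.0f, Chao1 %.0f, Shannon %.2f nats, coverage %.3f",
      mean(dv$s_obs), mean(dv$chao1), mean(dv$shannon), mean(dv$coverage)))

  if (!is.null(file)) writeLines(lines, file)
  cat(lines, sep = "\n")
  invisible(lines)
}
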