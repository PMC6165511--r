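#' Write a synthetic dataset to disk
#'
#' Writes the exchange files consumed by the analysis stages: a TSV taxon
#' table (taxon_id, lineage, one column per sample), CSV time courses, CSV
#' sample metadata, CSV kinetics ground truth and counts TSV, plus a JSON
#' manifest listing every file with its row count. All numbers are written
#' at full precision so a round trip reproduces values to 1e-12.
#'
#' @param dataset output of [simulate_dataset()].
#' @param directory target directory (created if absent).
#' @param overwrite overwrite an existing manifest; otherwise writing into
#'   a directory that already holds one is an error.
#' @return invisibly, the manifest as a named list.
#' @export
write_dataset <- function(dataset, directory, overwrite = FALSE) {
  if (is.null(dataset$table) || nrow(dataset$table$values) == 0L)
    stop_rf("empty sample set: nothing to write")
  manifest_path <- file.path(directory, "manifest.json")
  if (file.exists(manifest_path) && !overwrite)
    stop_rf("manifest already exists in ", directory,
            " (use overwrite = TRUE)")
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)

  write_table_tsv <- function(tab, path) {
    dt <- data.table::data.table(taxon_id = colnames(tab$values),
                                 lineage = tab$lineage)
    vals <- data.table::as.data.table(t(tab$values))
    data.table::fwrite(cbind(dt, vals), path, sep = "\t")
    nrow(dt)
  }

  files <- list()
  files$taxon_table <- list(file = "taxon_table.tsv",
                            rows = write_table_tsv(dataset$table,
                              file.path(directory, "taxon_table.tsv")))
  files$counts <- list(file = "counts.tsv",
                       rows = write_table_tsv(dataset$counts,
                         file.path(directory, "counts.tsv")))
  data.table::fwrite(dataset$timecourses,
                     file.path(directory, "timecourses.csv"))
  files$timecourses <- list(file = "timecourses.csv",
                            rows = nrow(dataset$timecourses))
  data.table::fwrite(dataset$table$metadata,
                     file.path(directory, "metadata.csv"))
  files$metadata <- list(file = "metadata.csv",
                         rows = nrow(dataset$table$metadata))
  data.table::fwrite(dataset$kinetics_truth,
                     file.path(directory, "kinetics_truth.csv"))
  files$kinetics_truth <- list(file = "kinetics_truth.csv",
                               rows = nrow(dataset$kinetics_truth))
  gt <- data.frame(taxon_id = names(dataset$truth$gamma),
                   gamma = unname(dataset$truth$gamma),
                   planted = names(dataset$truth$gamma) %in%
                     dataset$truth$planted_genus_ids)
  data.table::fwrite(gt, file.path(directory, "ground_truth.csv"))
  files$ground_truth <- list(file = "ground_truth.csv", rows = nrow(gt))

  manifest <- list(seed = dataset$config$seed, files = files)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Read back a dataset written by [write_dataset()]
#'
#' @param directory dataset directory containing `manifest.json`.
#' @return list with `table`, `counts`, `timecourses`, `metadata`,
#'   `kinetics_truth`, `ground_truth`, `manifest`.
#' @export
read_dataset <- function(directory) {
  manifest_path <- file.path(directory, "manifest.json")
  if (!file.exists(manifest_path))
    stop_rf("no manifest.json in ", directory)
  manifest <- jsonlite::read_json(manifest_path)
  rd <- function(f) data.table::fread(file.path(directory, f),
                                      data.table = FALSE)
  list(table = read_taxon_table(file.path(directory, "taxon_table.tsv")),
       counts = read_taxon_table(file.path(directory, "counts.tsv"),
                                 normalize = FALSE),
       timecourses = rd("timecourses.csv"),
       metadata = rd("metadata.csv"),
       kinetics_truth = rd("kinetics_truth.csv"),
       ground_truth = rd("ground_truth.csv"),
       manifest = manifest)
}
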