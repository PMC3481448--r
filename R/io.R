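# Plain-text serialization of the main data objects.

write_tsv_plain <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a digested catalog as TSV
#'
#' Columns: `peptide_id`, `sequence`, `mono_mass`, `rt`, `parent_ids`
#' (semicolon-joined), `is_unique`.
#'
#' @param catalog A digested `proteome_catalog`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_catalog_tsv <- function(catalog, path) {
  stopifnot(inherits(catalog, "proteome_catalog"))
  df <- tidy(catalog)[, c("peptide_id", "sequence", "mono_mass", "rt",
                          "parent_ids", "is_unique")]
  write_tsv_plain(df, path)
}

#' Write ground-truth samples as TSV
#'
#' Writes a wide concentration table (proteins x samples) and, next to it, a
#' `<path>.markers.tsv` manifest with per-protein control mean and fold.
#'
#' @param truth A `ground_truth_samples`.
#' @param path Output path of the concentration table.
#' @return The path, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth_samples"))
  wide <- data.frame(protein_id = truth$protein_ids,
                     truth$concentrations, check.names = FALSE)
  write_tsv_plain(wide, path)
  manifest <- data.frame(protein_id = truth$protein_ids, eta = truth$eta,
                         fold = truth$fold,
                         is_marker = seq_along(truth$eta) %in%
                           truth$marker_idx)
  write_tsv_plain(manifest, paste0(path, ".markers.tsv"))
  invisible(path)
}

#' Write an observed peptide table as long-format TSV
#'
#' Columns: `peptide_id`, `sample_id`, `abundance`, `detected`,
#' `identified`, `observed`.
#'
#' @param table An `observed_peptide_table`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_observed_tsv <- function(table, path) {
  stopifnot(inherits(table, "observed_peptide_table"))
  write_tsv_plain(tidy(table), path)
}

#' Write a run result as a one-row TSV and a JSON record
#'
#' @param result A `run_result`.
#' @param path Output TSV path; a JSON twin is written at `<path>.json`.
#' @return The path, invisibly.
#' @export
write_run_result <- function(result, path) {
  stopifnot(inherits(result, "run_result"))
  write_tsv_plain(glance(result), path)
  jsonlite::write_json(c(list(seed = result$seed, n_pep = result$n_pep),
                         as.list(result$indices)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write sweep results as long-format TSV
#'
#' @param sweep A `sweep_summary`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_sweep_tsv <- function(sweep, path) {
  stopifnot(inherits(sweep, "sweep_summary"))
  write_tsv_plain(sweep$results, path)
}
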