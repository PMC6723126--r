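#' Write an abundance matrix as TSV
#'
#' First column `feature_id`, remaining columns `<condition>_R<rep>`.
#' Missing protein values are written as empty fields.
#'
#' @param mat Numeric matrix with feature row names.
#' @param path Output path.
#' @export
write_abundance_tsv <- function(mat, path) {
  df <- data.frame(feature_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read an abundance matrix from TSV
#'
#' @param path TSV written by [write_abundance_tsv()] (first column feature
#'   ids; empty cells become `NA`).
#' @return Numeric matrix with feature row names.
#' @export
read_abundance_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = "")
  mat <- as.matrix(df[, -1, drop = FALSE])
  mode(mat) <- "numeric"
  rownames(mat) <- df[[1]]
  mat
}

#' Write a simulated dataset to disk
#'
#' Writes the transcript and protein matrices, the ground-truth table and a
#' JSON manifest (design, noise, kinetic parameter settings, seed) into a
#' directory.
#'
#' @param sim A [simulate_light_pulse()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_light_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "light_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(transcript = file.path(dir, "transcript_counts.tsv"),
             protein = file.path(dir, "protein_intensities.tsv"),
             truth = file.path(dir, "ground_truth.tsv"),
             manifest = file.path(dir, "simulation_manifest.json"))
  write_abundance_tsv(sim$transcript, paths["transcript"])
  write_abundance_tsv(sim$protein, paths["protein"])
  utils::write.table(sim$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest <- list(design = unclass(sim$design),
                   noise = unclass(sim$noise),
                   params = unclass(sim$params),
                   seed = sim$seed)
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(paths)
}

#' Write per-condition fold-change profiles as TSV
#'
#' One row per feature; per condition a `log2fc_` column plus `p_` (raw) and,
#' when present, `adjp_` (BH-adjusted) columns.
#'
#' @param profiles An `fc_profiles` object.
#' @param path Output path.
#' @export
write_profiles_tsv <- function(profiles, path) {
  stopifnot(inherits(profiles, "fc_profiles"))
  df <- data.frame(feature_id = rownames(profiles$log2fc),
                   stringsAsFactors = FALSE)
  for (cc in colnames(profiles$log2fc))
    df[[paste0("log2fc_", cc)]] <- profiles$log2fc[, cc]
  for (cc in colnames(profiles$raw_p))
    df[[paste0("p_", cc)]] <- profiles$raw_p[, cc]
  if (!is.null(profiles$adj_p))
    for (cc in colnames(profiles$adj_p))
      df[[paste0("adjp_", cc)]] <- profiles$adj_p[, cc]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write regulation calls as TSV
#'
#' @param calls A `regulation_calls` data.frame.
#' @param path Output path.
#' @export
write_calls_tsv <- function(calls, path) {
  utils::write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
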