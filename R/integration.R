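#' Match regulated transcripts with regulated proteins
#'
#' An mRNA/protein pair is a feature regulated in both layers. For every
#' regulated transcript the result also records whether any protein
#' quantitation exists at all (membership in the evaluated protein universe),
#' the distinction behind "mRNA change without protein change" versus "no
#' protein data".
#'
#' @param transcript_calls,protein_calls `regulation_calls` data.frames (or
#'   character vectors of regulated feature ids).
#' @param protein_universe Character vector of all proteins with quantitative
#'   data. Defaults to all features in `protein_calls` when that is a calls
#'   data.frame.
#' @return List of class `pair_match`: `pairs` (ids regulated in both
#'   layers), `transcript_flags` (data.frame: `feature_id`,
#'   `has_protein_data`, `is_pair` for every regulated transcript).
#' @export
match_pairs <- function(transcript_calls, protein_calls, protein_universe = NULL) {
  t_reg <- .regulated_ids(transcript_calls)
  p_reg <- .regulated_ids(protein_calls)
  if (is.null(protein_universe)) protein_universe <- .universe_ids(protein_calls)
  if (anyDuplicated(t_reg) || anyDuplicated(p_reg) || anyDuplicated(protein_universe))
    stop("duplicate feature ids")
  pairs <- intersect(t_reg, p_reg)
  flags <- data.frame(feature_id = t_reg,
                      has_protein_data = t_reg %in% protein_universe,
                      is_pair = t_reg %in% pairs,
                      stringsAsFactors = FALSE)
  structure(list(pairs = pairs, transcript_flags = flags),
            class = "pair_match")
}

#' @export
print.pair_match <- function(x, ...) {
  cat(sprintf("pair_match: %d mRNA/protein pairs; %d regulated transcripts (%d with protein data)\n",
              length(x$pairs), nrow(x$transcript_flags),
              sum(x$transcript_flags$has_protein_data)))
  invisible(x)
}

.regulated_ids <- function(x) {
  if (is.data.frame(x)) x$feature_id[x$regulated] else as.character(x)
}
.universe_ids <- function(x) {
  if (is.data.frame(x)) x$feature_id else as.character(x)
}

#' Partition regulated features into regulatory categories
#'
#' Splits the two regulated sets into: mRNA/protein pairs (regulated in
#' both), protein-only changes, mRNA changes with protein data but no protein
#' change (post-transcriptionally buffered candidates), and mRNA changes for
#' which no protein was quantified. The partition identities
#' `pairs + mrna_only_with_protein_data + mrna_only_no_protein_data =
#' mrna_regulated` and `pairs + protein_only = protein_regulated` hold by
#' construction and are validated.
#'
#' @inheritParams match_pairs
#' @param mrna_universe Character vector of all evaluated transcripts
#'   (defaults to all features in `transcript_calls`).
#' @param n_genome Number of genes in the genome (>= evaluated counts).
#' @return List of class `category_partition` with fields `n_genome`,
#'   `n_mrna_evaluated`, `n_protein_evaluated`, `n_mrna_regulated`,
#'   `n_protein_regulated`, `n_pairs`, `n_protein_only`,
#'   `n_mrna_only_with_protein_data`, `n_mrna_only_no_protein_data`.
#' @export
partition_categories <- function(transcript_calls, protein_calls,
                                 mrna_universe = NULL, protein_universe = NULL,
                                 n_genome) {
  t_reg <- .regulated_ids(transcript_calls)
  p_reg <- .regulated_ids(protein_calls)
  if (is.null(mrna_universe)) mrna_universe <- .universe_ids(transcript_calls)
  if (is.null(protein_universe)) protein_universe <- .universe_ids(protein_calls)
  if (!all(t_reg %in% mrna_universe))
    stop("regulated transcript outside the evaluated mRNA universe")
  if (!all(p_reg %in% protein_universe))
    stop("regulated protein outside the evaluated protein universe")
  if (n_genome < max(length(mrna_universe), length(protein_universe)))
    stop("n_genome smaller than an evaluated universe")
  pairs <- intersect(t_reg, p_reg)
  with_pdata <- setdiff(intersect(t_reg, protein_universe), pairs)
  no_pdata <- setdiff(t_reg, protein_universe)
  out <- list(n_genome = n_genome,
              n_mrna_evaluated = length(mrna_universe),
              n_protein_evaluated = length(protein_universe),
              n_mrna_regulated = length(t_reg),
              n_protein_regulated = length(p_reg),
              n_pairs = length(pairs),
              n_protein_only = length(p_reg) - length(pairs),
              n_mrna_only_with_protein_data = length(with_pdata),
              n_mrna_only_no_protein_data = length(no_pdata))
  stopifnot(out$n_pairs + out$n_mrna_only_with_protein_data +
              out$n_mrna_only_no_protein_data == out$n_mrna_regulated,
            out$n_pairs + out$n_protein_only == out$n_protein_regulated)
  structure(out, class = "category_partition")
}

#' @export
print.category_partition <- function(x, ...) {
  cat("Regulatory-category partition\n")
  cat(sprintf("  genome %d; evaluated: %d mRNAs, %d proteins\n",
              x$n_genome, x$n_mrna_evaluated, x$n_protein_evaluated))
  cat(sprintf("  regulated: %d mRNAs, %d proteins; %d mRNA/protein pairs\n",
              x$n_mrna_regulated, x$n_protein_regulated, x$n_pairs))
  cat(sprintf("  protein change without mRNA change: %d\n", x$n_protein_only))
  cat(sprintf("  mRNA change without protein change: %d (+ %d with no protein data)\n",
              x$n_mrna_only_with_protein_data, x$n_mrna_only_no_protein_data))
  invisible(x)
}

#' Lag correlation grid between transcript and protein fold-changes
#'
#' Cell `(i, j)` holds the Pearson correlation, over the mRNA/protein pairs,
#' between transcript log2 fold-change at condition `i` and protein log2
#' fold-change at condition `j`. Both `r` and `r^2` are stored; a cell where
#' either coordinate is constant across pairs is undefined and reported as
#' `NA`.
#'
#' @param pairs A [match_pairs()] result or character vector of pair ids
#'   (>= 3 required).
#' @param transcript_profiles,protein_profiles `fc_profiles` of the two
#'   layers containing all pair features.
#' @return List of class `lag_grid`: matrices `r`, `r2` (transcript
#'   conditions x protein conditions), `n` (pair count), and the two layers'
#'   condition minutes.
#' @export
lag_correlation <- function(pairs, transcript_profiles, protein_profiles) {
  ids <- if (inherits(pairs, "pair_match")) pairs$pairs else as.character(pairs)
  if (length(ids) < 3) stop("need >= 3 pairs for a stable correlation")
  stopifnot(inherits(transcript_profiles, "fc_profiles"),
            inherits(protein_profiles, "fc_profiles"))
  ct <- design_conditions(transcript_profiles$design, "transcript")
  cp <- design_conditions(protein_profiles$design, "protein")
  tc <- ct$condition[!ct$is_control]
  pc <- cp$condition[!cp$is_control]
  if (!all(ids %in% rownames(transcript_profiles$log2fc)) ||
      !all(ids %in% rownames(protein_profiles$log2fc)))
    stop("pair feature missing from a profile matrix")
  X <- transcript_profiles$log2fc[ids, tc, drop = FALSE]
  Y <- protein_profiles$log2fc[ids, pc, drop = FALSE]
  r <- matrix(NA_real_, length(tc), length(pc), dimnames = list(tc, pc))
  for (i in seq_along(tc)) for (j in seq_along(pc)) {
    x <- X[, i]; y <- Y[, j]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    r[i, j] <- stats::cor(x, y)
  }
  structure(list(r = r, r2 = r^2,
                 n = matrix(length(ids), length(tc), length(pc),
                            dimnames = list(tc, pc)),
                 transcript_minutes = ct$minutes[match(tc, ct$condition)],
                 protein_minutes = cp$minutes[match(pc, cp$condition)]),
            class = "lag_grid")
}

#' @export
print.lag_grid <- function(x, ...) {
  cat(sprintf("lag_grid over %d pairs (Pearson r):\n", x$n[1, 1]))
  print(round(x$r, 2))
  invisible(x)
}

#' Estimate the mRNA-to-protein delay from a lag grid
#'
#' Returns `protein_time(j*) - transcript_time(i*)` for the cell maximizing
#' `r^2`; ties are resolved toward the smallest lag (then the earliest
#' transcript time). Per-transcript-condition best lags are also reported.
#'
#' @param grid A [lag_correlation()] result with at least one defined cell.
#' @return List of class `peak_lag`: `lag_minutes`, `transcript_condition`,
#'   `protein_condition`, `r2`, `by_row` (data.frame of per-row best lags).
#' @export
estimate_peak_lag <- function(grid) {
  stopifnot(inherits(grid, "lag_grid"))
  if (all(is.na(grid$r2))) stop("all grid cells undefined")
  lagm <- outer(grid$transcript_minutes, grid$protein_minutes,
                function(ti, tj) tj - ti)
  best <- which(grid$r2 == max(grid$r2, na.rm = TRUE), arr.ind = TRUE)
  if (nrow(best) > 1) {
    o <- order(lagm[best], grid$transcript_minutes[best[, 1]])
    best <- best[o[1], , drop = FALSE]
  }
  i <- best[1, 1]; j <- best[1, 2]
  by_row <- do.call(rbind, lapply(seq_len(nrow(grid$r2)), function(ii) {
    if (all(is.na(grid$r2[ii, ]))) return(NULL)
    jj <- which(grid$r2[ii, ] == max(grid$r2[ii, ], na.rm = TRUE))
    jj <- jj[which.min(lagm[ii, jj])]
    data.frame(transcript_condition = rownames(grid$r2)[ii],
               protein_condition = colnames(grid$r2)[jj],
               lag_minutes = lagm[ii, jj], r2 = grid$r2[ii, jj],
               stringsAsFactors = FALSE)
  }))
  structure(list(lag_minutes = lagm[i, j],
                 transcript_condition = rownames(grid$r2)[i],
                 protein_condition = colnames(grid$r2)[j],
                 r2 = grid$r2[i, j], by_row = by_row),
            class = "peak_lag")
}

#' @export
print.peak_lag <- function(x, ...) {
  cat(sprintf("peak lag: %g min (mRNA %s -> protein %s, r^2 = %.2f)\n",
              x$lag_minutes, x$transcript_condition, x$protein_condition, x$r2))
  invisible(x)
}

#' Export paired mRNA/protein fold-change profiles
#'
#' Long-format table of the non-control log2 fold-changes of each pair in
#' both layers, suitable for dual-axis time-course plots. Rows are ordered by
#' feature, then layer (transcript first), then minutes.
#'
#' @inheritParams lag_correlation
#' @return data.frame with columns `feature_id`, `layer`, `condition`,
#'   `minutes`, `log2fc`.
#' @export
paired_profile_export <- function(pairs, transcript_profiles, protein_profiles) {
  ids <- if (inherits(pairs, "pair_match")) pairs$pairs else as.character(pairs)
  ids <- sort(ids)
  layers <- list(transcript = transcript_profiles, protein = protein_profiles)
  out <- do.call(rbind, lapply(ids, function(id) {
    do.call(rbind, lapply(names(layers), function(ly) {
      prof <- layers[[ly]]
      conds <- design_conditions(prof$design, ly)
      nc <- conds[!conds$is_control, , drop = FALSE]
      data.frame(feature_id = id, layer = ly, condition = nc$condition,
                 minutes = nc$minutes,
                 log2fc = prof$log2fc[id, nc$condition],
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}
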