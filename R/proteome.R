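#' Variance-stabilizing (glog) transform of protein intensities
#'
#' Per-sample affine calibration followed by an arsinh generalized-log:
#' `y = asinh((x - a_s) / (b_s / gain)) / log(2)`. The location `a_s` is the
#' sample median minus `shift_mads` MADs, clipped so the argument stays
#' nonnegative, and the scale is the sample median absolute deviation `b_s`
#' divided by a fixed `gain`. The MAD makes samples comparable in location
#' and scale (removing per-run multiplicative offsets), while the gain places
#' the arsinh's linear region at a small fraction of the sample's spread, so
#' that only near-background intensities are damped — for everything else
#' differences approach log2 ratios (`asinh(x) -> ln(2x)` for large `x`).
#' The transform is strictly monotone within each sample.
#'
#' @param mat Nonnegative protein intensity matrix (features x samples),
#'   `NA` = not detected in that run.
#' @param shift_mads Fixed multiple of the MAD used for the location offset.
#' @param gain Ratio of the sample MAD to the glog linear-region scale
#'   (default 50: intensities above ~2% of the sample spread are on the log
#'   scale).
#' @return Transformed matrix on the glog2 scale, with the per-sample
#'   calibration in `attr(, "calibration")`.
#' @export
vst_transform <- function(mat, shift_mads = 3, gain = 50) {
  stopifnot(is.matrix(mat), is.numeric(mat), gain > 0)
  if (any(mat < 0, na.rm = TRUE)) stop("negative intensities")
  calib <- matrix(NA_real_, ncol(mat), 2,
                  dimnames = list(colnames(mat), c("a", "b")))
  out <- mat
  for (j in seq_len(ncol(mat))) {
    x <- mat[, j]
    med <- stats::median(x, na.rm = TRUE)
    b <- stats::mad(x, na.rm = TRUE)
    if (!is.finite(b) || b == 0) {
      warning(sprintf("sample %s has zero MAD; using scale 1", colnames(mat)[j]))
      b <- 1
    }
    # location offset: background shift, clipped into [0, min(x)] so the
    # arsinh argument is nonnegative and large intensities keep log2 ratios
    a <- max(0, min(med - shift_mads * b, min(x, na.rm = TRUE)))
    out[, j] <- asinh((x - a) * gain / b) / log(2)
    calib[j, ] <- c(a, b / gain)
  }
  attr(out, "calibration") <- calib
  out
}

#' Remove per-run (batch) offsets
#'
#' Each protein replicate is one labelling run containing every condition, so
#' the additive model `value = condition effect + batch effect` is balanced
#' and the least-squares batch effect of run `r` is the protein's mean over
#' that run minus its grand mean. These effects (which sum to zero across the
#' runs in which the protein was observed) are subtracted; condition
#' contrasts are unchanged. Proteins absent from entire runs are corrected
#' using their observed runs only.
#'
#' @param mat Matrix on the transformed scale (features x samples).
#' @param batch Per-sample batch/run labels (defaults to the `_R<k>` suffix of
#'   the column names).
#' @return Corrected matrix.
#' @export
remove_batch <- function(mat, batch = sub("^.*_(R[0-9]+)$", "\\1", colnames(mat))) {
  stopifnot(is.matrix(mat), length(batch) == ncol(mat))
  runs <- unique(batch)
  if (length(runs) < 2) return(mat)
  obs <- !is.na(mat)
  # per-protein per-run means over observed cells
  run_sum <- sapply(runs, function(r) rowSums(mat[, batch == r, drop = FALSE], na.rm = TRUE))
  run_n <- sapply(runs, function(r) rowSums(obs[, batch == r, drop = FALSE]))
  run_mean <- run_sum / run_n                       # NaN where run unobserved
  grand <- rowSums(run_sum) / rowSums(run_n)
  eff <- run_mean - rowMeans(run_mean, na.rm = TRUE)
  eff[is.nan(eff)] <- 0
  mat - eff[, match(batch, runs), drop = FALSE]
}

#' Filter proteins by replicate-run presence
#'
#' A protein is "detected" in a run when at least one of that run's samples
#' carries a value. Only proteins detected in at least `min_runs` runs are
#' analysed — the "found in two or three experiments" rule — and the
#' per-protein presence pattern is recorded so replicate-overlap (Venn)
#' counts can be reported.
#'
#' @param mat Protein matrix (features x samples), `NA` = absent.
#' @param batch Per-sample run labels (default from column-name suffix).
#' @param min_runs Minimum number of runs (default 2).
#' @return List of class `presence_filter`: `matrix` (kept proteins),
#'   `presence` (data.frame: `protein_id`, `detected_in`, `n_detected`,
#'   `kept`), `overlap` (named counts per run combination).
#' @export
filter_presence <- function(mat, batch = sub("^.*_(R[0-9]+)$", "\\1", colnames(mat)),
                            min_runs = 2) {
  stopifnot(is.matrix(mat))
  runs <- unique(batch)
  det <- sapply(runs, function(r) rowSums(!is.na(mat[, batch == r, drop = FALSE])) > 0)
  if (is.null(dim(det))) det <- matrix(det, nrow = nrow(mat), dimnames = list(rownames(mat), runs))
  n_det <- rowSums(det)
  kept <- n_det >= min_runs
  pattern <- apply(det, 1, function(z) paste(runs[z], collapse = "+"))
  presence <- data.frame(protein_id = rownames(mat),
                         detected_in = pattern,
                         n_detected = n_det,
                         kept = kept,
                         stringsAsFactors = FALSE)
  overlap <- table(pattern[n_det > 0])
  structure(list(matrix = mat[kept, , drop = FALSE],
                 presence = presence,
                 overlap = as.list(overlap),
                 min_runs = min_runs, runs = runs),
            class = "presence_filter")
}

#' @export
print.presence_filter <- function(x, ...) {
  cat(sprintf("presence filter (>= %d of %d runs): kept %d of %d proteins\n",
              x$min_runs, length(x$runs), nrow(x$matrix), nrow(x$presence)))
  invisible(x)
}

#' k-nearest-neighbour imputation of missing runs
#'
#' For a protein missing some columns, the `k` fully observed proteins
#' nearest in Euclidean distance over the target's observed columns act as
#' neighbours; the imputed value is their inverse-distance-weighted mean in
#' the missing columns (a simple mean over exact matches when any distance is
#' zero). Observed entries are never altered.
#'
#' @param mat Protein matrix on the transformed scale.
#' @param k Number of neighbours (default 10).
#' @return Complete matrix.
#' @export
knn_impute <- function(mat, k = 10) {
  stopifnot(is.matrix(mat), k >= 1)
  miss_rows <- which(rowSums(is.na(mat)) > 0)
  if (!length(miss_rows)) return(mat)
  complete <- mat[rowSums(is.na(mat)) == 0, , drop = FALSE]
  if (nrow(complete) == 0) stop("no fully observed proteins to impute from")
  if (nrow(complete) < k) {
    warning(sprintf("only %d complete proteins available; using all", nrow(complete)))
    k <- nrow(complete)
  }
  out <- mat
  for (i in miss_rows) {
    obs <- which(!is.na(mat[i, ]))
    if (!length(obs)) stop("protein with no observed values")
    d2 <- colSums((t(complete[, obs, drop = FALSE]) - mat[i, obs])^2)
    nb <- order(d2)[seq_len(k)]
    d <- sqrt(d2[nb])
    w <- if (any(d == 0)) as.numeric(d == 0) else 1 / d
    w <- w / sum(w)
    fill <- colSums(complete[nb, -obs, drop = FALSE] * w)
    out[i, -obs] <- fill
  }
  out
}

#' Moderated per-condition tests and fold-changes for the protein layer
#'
#' For each non-control condition, forms the within-run paired differences
#' `x[condition, run] - x[control, run]` on the glog2 scale (so the mean
#' difference is the log2 fold-change), then applies a moderated one-sample
#' t-test: the per-protein variance is smoothed toward the across-protein
#' mean variance with weight `moderation_weight`, and the implied prior
#' degrees of freedom `d0 = w (n-1) / (1-w)` are added to the residual
#' degrees of freedom. Weight 0 recovers the ordinary one-sample t-test.
#' Benjamini-Hochberg adjustment is applied across proteins within each
#' condition.
#'
#' @param mat Complete protein matrix on the transformed scale.
#' @param design A [pulse_design()].
#' @param moderation_weight Smoothing weight in `[0, 1)` (default 0.75,
#'   implying prior degrees of freedom `2(n-1)` for triplicate runs;
#'   near-homogeneous reporter-ion variances justify strong pooling).
#' @return An `fc_profiles` object (see [fold_changes()]) with `adj_p` filled.
#' @export
protein_profiles <- function(mat, design, moderation_weight = 0.75) {
  st <- .match_samples(mat, design, "protein")
  if (anyNA(mat)) stop("protein matrix must be complete (run knn_impute first)")
  if (moderation_weight < 0 || moderation_weight >= 1)
    stop("moderation_weight must be in [0, 1)")
  conds <- design_conditions(design, "protein")
  noncontrol <- conds$condition[!conds$is_control]
  reps <- sort(unique(st$replicate))
  n <- length(reps)
  if (n < 2) stop("need >= 2 replicates")
  ctrl_cols <- st$sample[st$is_control][order(st$replicate[st$is_control])]
  log2fc <- matrix(0, nrow(mat), nrow(conds),
                   dimnames = list(rownames(mat), conds$condition))
  raw_p <- adj_p <- matrix(NA_real_, nrow(mat), length(noncontrol),
                           dimnames = list(rownames(mat), noncontrol))
  for (cc in noncontrol) {
    cols <- st$sample[st$condition == cc][order(st$replicate[st$condition == cc])]
    D <- mat[, cols, drop = FALSE] - mat[, ctrl_cols, drop = FALSE]
    dbar <- rowMeans(D)
    s2 <- apply(D, 1, stats::var)
    s2_tilde <- moderation_weight * mean(s2) + (1 - moderation_weight) * s2
    d0 <- moderation_weight * (n - 1) / (1 - moderation_weight)
    se <- sqrt(s2_tilde / n)
    p <- numeric(length(dbar))
    zero <- se == 0
    p[zero] <- ifelse(dbar[zero] == 0, 1, 0)
    p[!zero] <- 2 * stats::pt(-abs(dbar[!zero] / se[!zero]), df = n - 1 + d0)
    log2fc[, cc] <- dbar
    raw_p[, cc] <- p
    adj_p[, cc] <- stats::p.adjust(p, method = "BH")
  }
  structure(list(log2fc = log2fc, raw_p = raw_p, adj_p = adj_p,
                 n_obs = stats::setNames(rep(n, nrow(conds)), conds$condition),
                 layer = "protein", design = design,
                 moderation_weight = moderation_weight),
            class = "fc_profiles")
}

#' Call light-regulated proteins
#'
#' A protein is regulated when at least one condition satisfies both
#' `adj_p < fdr` and `|log2fc| >= log2(fc_threshold)` — the "twofold relative
#' to the dark control at FDR < 0.05" rule. Peak selection follows the
#' transcript layer; `peak_is_final` flags peaks at the last sampled time
#' point.
#'
#' @param profiles A [protein_profiles()] result.
#' @param fdr Benjamini-Hochberg adjusted p-value cutoff (default 0.05).
#' @param fc_threshold Fold-change cutoff on the linear scale (default 2).
#' @return A `regulation_calls` data.frame with `peak_is_final` column.
#' @export
call_regulated_proteins <- function(profiles, fdr = 0.05, fc_threshold = 2) {
  stopifnot(inherits(profiles, "fc_profiles"), profiles$layer == "protein")
  if (is.null(profiles$adj_p)) stop("profiles carry no adjusted p-values")
  conds <- design_conditions(profiles$design, "protein")
  noncontrol <- conds$condition[!conds$is_control]
  minutes <- conds$minutes[match(noncontrol, conds$condition)]
  out <- .call_regulated(profiles$log2fc[, noncontrol, drop = FALSE],
                         profiles$adj_p[, noncontrol, drop = FALSE],
                         minutes, fdr, log2(fc_threshold),
                         rownames(profiles$log2fc), timing_boundary = NULL,
                         final_minutes = max(minutes))
  attr(out, "layer") <- "protein"
  attr(out, "thresholds") <- c(fdr = fdr, fc = fc_threshold)
  out
}

#' Peak-time summary of regulated proteins
#'
#' Fraction of regulated proteins whose abundance change peaks at the final
#' sampled time point, reported as a percent rounded half-up to one decimal.
#'
#' @param calls Protein-layer `regulation_calls`.
#' @return List: `n_regulated`, `n_final`, `n_earlier`, `final_pct`.
#' @export
peak_time_summary <- function(calls) {
  stopifnot(is.data.frame(calls), "peak_is_final" %in% names(calls))
  reg <- calls[calls$regulated, , drop = FALSE]
  n_final <- sum(reg$peak_is_final)
  list(n_regulated = nrow(reg), n_final = n_final,
       n_earlier = nrow(reg) - n_final,
       final_pct = if (nrow(reg)) .round_halfup(100 * n_final / nrow(reg), 1) else 0)
}

#' Run the full proteome processing chain
#'
#' Fixed stage order: variance stabilisation, batch-offset removal,
#' replicate-presence filtering, kNN imputation, moderated testing, and
#' regulation calling. The order is part of the method's contract and is
#' recorded in the result.
#'
#' @param mat Raw protein intensity matrix (features x samples, `NA` =
#'   absent from that run).
#' @param design A [pulse_design()].
#' @param min_runs,knn_k,fdr,fc_threshold,moderation_weight Stage parameters.
#' @return List of class `proteome_result`: `profiles`, `calls`, `presence`,
#'   `imputed`, `stages`.
#' @export
proteome_pipeline <- function(mat, design, min_runs = 2, knn_k = 10,
                              fdr = 0.05, fc_threshold = 2,
                              moderation_weight = 0.75) {
  v <- vst_transform(mat)
  b <- remove_batch(v)
  f <- filter_presence(b, min_runs = min_runs)
  imp <- knn_impute(f$matrix, k = knn_k)
  prof <- protein_profiles(imp, design, moderation_weight)
  calls <- call_regulated_proteins(prof, fdr = fdr, fc_threshold = fc_threshold)
  structure(list(profiles = prof, calls = calls, presence = f, imputed = imp,
                 stages = c("vst", "batch", "presence", "impute", "test", "call")),
            class = "proteome_result")
}

#' @export
print.proteome_result <- function(x, ...) {
  cat(sprintf("proteome_result: %d proteins analysed, %d regulated\n",
              nrow(x$imputed), sum(x$calls$regulated)))
  invisible(x)
}
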