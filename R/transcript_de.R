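#' Median-of-ratios library-size normalization
#'
#' Scales each sample by the median ratio of its values to the per-feature
#' geometric mean, the standard size-factor estimator for count matrices.
#' Features containing any zero are excluded from factor estimation. Factors
#' are rescaled to have median 1, so a matrix without library-size effects is
#' returned unchanged and a single distorted sample receives exactly its
#' distortion as factor.
#'
#' @param mat Nonnegative numeric matrix, features x samples, no missing
#'   values (transcript layer).
#' @return The normalized matrix, with the per-sample factors in
#'   `attr(, "size_factors")`.
#' @export
normalize_library <- function(mat) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (anyNA(mat)) stop("transcript matrix must not contain missing values")
  if (any(mat < 0)) stop("negative abundances")
  if (all(mat == 0)) stop("all-zero matrix")
  pos <- rowSums(mat == 0) == 0
  if (!any(pos)) stop("no zero-free features; cannot estimate size factors")
  lg <- log(mat[pos, , drop = FALSE])
  geo <- rowMeans(lg)
  sf <- exp(apply(lg - geo, 2, stats::median))
  sf <- sf / stats::median(sf)           # median factor 1
  out <- sweep(mat, 2, sf, "/")
  attr(out, "size_factors") <- sf
  out
}

# map matrix columns onto a layer's sample table; errors on mismatch
.match_samples <- function(mat, design, layer) {
  st <- sample_table(design, layer)
  missing <- setdiff(st$sample, colnames(mat))
  if (length(missing))
    stop("matrix is missing design samples: ", paste(missing, collapse = ", "))
  st
}

# vectorized Welch two-sample t on rows; zero-variance convention:
# p = 1 when the group means are equal, p = 0 when they differ exactly
.welch_rows <- function(x, y) {
  n1 <- ncol(x); n2 <- ncol(y)
  if (n1 < 2 || n2 < 2) stop("need >= 2 replicates per group")
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- apply(x, 1, stats::var); v2 <- apply(y, 1, stats::var)
  se2 <- v1 / n1 + v2 / n2
  p <- numeric(length(m1))
  zero <- se2 == 0
  p[zero] <- ifelse(m1[zero] == m2[zero], 1, 0)
  if (any(!zero)) {
    tt <- (m1[!zero] - m2[!zero]) / sqrt(se2[!zero])
    df <- se2[!zero]^2 / ((v1[!zero] / n1)^2 / (n1 - 1) + (v2[!zero] / n2)^2 / (n2 - 1))
    p[!zero] <- 2 * stats::pt(-abs(tt), df)
  }
  p
}

#' Welch test of one condition against the dark control
#'
#' Two-sided Welch two-sample t-test per feature on `log2(x + pseudocount)`,
#' comparing the replicates of `condition` with those of the control. When
#' both groups have zero variance the p-value is 1 if the means are equal and
#' 0 otherwise.
#'
#' @param mat Normalized transcript matrix (features x samples).
#' @param design A [pulse_design()].
#' @param condition A non-control condition label present in the design.
#' @param pseudocount Added before taking logs (default 1).
#' @return Numeric vector of raw p-values, one per feature.
#' @export
test_condition <- function(mat, design, condition, pseudocount = 1) {
  st <- .match_samples(mat, design, "transcript")
  conds <- design_conditions(design, "transcript")
  if (!condition %in% conds$condition[!conds$is_control])
    stop(sprintf("condition '%s' not in design", condition))
  lx <- log2(mat + pseudocount)
  a <- lx[, st$sample[st$condition == condition], drop = FALSE]
  b <- lx[, st$sample[st$condition == design$control_label], drop = FALSE]
  .welch_rows(a, b)
}

#' Per-condition log2 fold-changes and tests versus the dark control
#'
#' For every feature and condition, computes the mean over replicates of
#' `log2(x + pseudocount)` minus the same quantity in the control, together
#' with the Welch test p-value of [test_condition()]. The control condition's
#' fold-change is identically zero.
#'
#' @inheritParams test_condition
#' @return Object of class `fc_profiles`: list with `log2fc` (features x all
#'   conditions, control column = 0), `raw_p` (features x non-control
#'   conditions), `adj_p` (`NULL` for the transcript layer), `n_obs`,
#'   `layer`, `design`.
#' @export
fold_changes <- function(mat, design, pseudocount = 1) {
  st <- .match_samples(mat, design, "transcript")
  conds <- design_conditions(design, "transcript")
  lx <- log2(mat + pseudocount)
  cond_means <- sapply(conds$condition, function(cc)
    rowMeans(lx[, st$sample[st$condition == cc], drop = FALSE]))
  ctrl <- design$control_label
  log2fc <- cond_means - cond_means[, ctrl]
  log2fc[, ctrl] <- 0
  noncontrol <- conds$condition[!conds$is_control]
  raw_p <- sapply(noncontrol, function(cc) test_condition(mat, design, cc, pseudocount))
  if (is.null(dim(raw_p))) raw_p <- matrix(raw_p, nrow = nrow(mat),
                                           dimnames = list(rownames(mat), noncontrol))
  n_obs <- sapply(conds$condition, function(cc) sum(st$condition == cc))
  structure(list(log2fc = log2fc, raw_p = raw_p, adj_p = NULL, n_obs = n_obs,
                 layer = "transcript", design = design,
                 pseudocount = pseudocount),
            class = "fc_profiles")
}

#' @export
print.fc_profiles <- function(x, ...) {
  cat(sprintf("fc_profiles [%s layer]: %d features x %d conditions (control %s)\n",
              x$layer, nrow(x$log2fc), ncol(x$log2fc), x$design$control_label))
  invisible(x)
}

#' Early/late classification of regulated features
#'
#' A regulated feature is "early" when its peak response occurs at or before
#' `boundary` minutes after the pulse (inclusive) and "late" otherwise.
#'
#' @param calls A `regulation_calls` data.frame (see [call_regulated_transcripts()]);
#'   all rows must be regulated.
#' @param boundary Early/late boundary in minutes (default 25, inclusive).
#' @return Character vector, `"early"` or `"late"`.
#' @export
classify_timing <- function(calls, boundary = 25) {
  if (is.data.frame(calls)) {
    if (any(!calls$regulated)) stop("classify_timing: unregulated feature")
    minutes <- calls$peak_minutes
  } else minutes <- calls
  if (anyNA(minutes)) stop("classify_timing: missing peak time")
  ifelse(minutes <= boundary, "early", "late")
}

# shared regulation-calling core: peak among conditions passing both cutoffs,
# ties broken by the earliest time point
.call_regulated <- function(log2fc, pmat, minutes, p_cut, lfc_cut,
                            feature_ids, timing_boundary, final_minutes = NULL) {
  ord <- order(minutes)
  qualifies <- (pmat < p_cut) & (abs(log2fc) >= lfc_cut)
  qualifies[is.na(qualifies)] <- FALSE
  regulated <- rowSums(qualifies) > 0
  peak_cond <- rep(NA_character_, length(regulated))
  peak_min <- rep(NA_real_, length(regulated))
  peak_lfc <- rep(NA_real_, length(regulated))
  conds <- colnames(log2fc)
  for (i in which(regulated)) {
    q <- which(qualifies[i, ])
    best <- q[abs(log2fc[i, q]) == max(abs(log2fc[i, q]))]
    if (length(best) > 1) best <- best[which.min(minutes[best])]
    peak_cond[i] <- conds[best]
    peak_min[i] <- minutes[best]
    peak_lfc[i] <- log2fc[i, best]
  }
  out <- data.frame(
    feature_id = feature_ids,
    regulated = regulated,
    direction = ifelse(regulated, ifelse(peak_lfc > 0, "up", "down"), NA_character_),
    peak_condition = peak_cond,
    peak_minutes = peak_min,
    peak_log2fc = peak_lfc,
    stringsAsFactors = FALSE)
  if (!is.null(timing_boundary)) {
    out$timing <- "none"
    out$timing[regulated] <- classify_timing(peak_min[regulated], timing_boundary)
  }
  if (!is.null(final_minutes)) {
    out$peak_is_final <- ifelse(regulated, peak_min == final_minutes, NA)
  }
  class(out) <- c("regulation_calls", "data.frame")
  out
}

#' Call light-regulated transcripts
#'
#' A transcript is regulated when at least one non-control condition satisfies
#' both `raw_p < p_threshold` and `|log2fc| >= log2(fc_threshold)` — the
#' "P < 0.01 and twofold, in at least one time point" rule. The peak condition
#' is the qualifying condition with the largest `|log2fc|` (ties go to the
#' earliest time point); `direction` is the sign of the peak fold-change and
#' `timing` classifies the peak as early or late.
#'
#' @param profiles A transcript-layer [fold_changes()] result.
#' @param p_threshold Raw p-value cutoff (default 0.01).
#' @param fc_threshold Fold-change cutoff on the linear scale (default 2).
#' @param timing_boundary Minutes boundary passed to [classify_timing()].
#' @return A `regulation_calls` data.frame with one row per feature:
#'   `feature_id`, `regulated`, `direction`, `peak_condition`, `peak_minutes`,
#'   `peak_log2fc`, `timing`.
#' @export
call_regulated_transcripts <- function(profiles, p_threshold = 0.01,
                                       fc_threshold = 2, timing_boundary = 25) {
  stopifnot(inherits(profiles, "fc_profiles"), profiles$layer == "transcript")
  conds <- design_conditions(profiles$design, "transcript")
  noncontrol <- conds$condition[!conds$is_control]
  minutes <- conds$minutes[match(noncontrol, conds$condition)]
  out <- .call_regulated(profiles$log2fc[, noncontrol, drop = FALSE],
                         profiles$raw_p[, noncontrol, drop = FALSE],
                         minutes, p_threshold, log2(fc_threshold),
                         rownames(profiles$log2fc), timing_boundary)
  attr(out, "layer") <- "transcript"
  attr(out, "thresholds") <- c(p = p_threshold, fc = fc_threshold)
  out
}

#' Principal component summary of fold-change profiles
#'
#' Centered PCA of the log2 fold-change matrix with conditions as
#' observations, summarising which time points dominate the response. The
#' sign of each component is fixed by requiring its first loading to be
#' nonnegative.
#'
#' @param profiles An [fold_changes()] result (either layer).
#' @param include_control Include the control condition (an all-zero profile
#'   anchoring the origin)? Default TRUE.
#' @return List of class `pca_summary`: `scores` (conditions x components),
#'   `explained` (variance fractions), `rotation`, `center`.
#' @export
pca_summary <- function(profiles, include_control = TRUE) {
  stopifnot(inherits(profiles, "fc_profiles"))
  X <- t(profiles$log2fc)                     # conditions x features
  if (!include_control)
    X <- X[rownames(X) != profiles$design$control_label, , drop = FALSE]
  if (nrow(X) < 2 || ncol(X) < 2) stop("need >= 2 conditions and >= 2 features")
  if (all(abs(sweep(X, 2, colMeans(X))) < .Machine$double.eps * 100))
    stop("constant matrix: no variance to decompose")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  flip <- ifelse(pc$rotation[1, ] < 0, -1, 1)
  pc$rotation <- sweep(pc$rotation, 2, flip, "*")
  pc$x <- sweep(pc$x, 2, flip, "*")
  structure(list(scores = pc$x, explained = pc$sdev^2 / sum(pc$sdev^2),
                 rotation = pc$rotation, center = pc$center),
            class = "pca_summary")
}

#' @export
print.pca_summary <- function(x, ...) {
  cat("PCA of fold-change profiles (conditions as observations)\n")
  ev <- round(100 * x$explained[1:min(2, length(x$explained))], 1)
  cat(sprintf("  PC1 %.1f%%, PC2 %.1f%% of variance\n", ev[1],
              ifelse(length(ev) > 1, ev[2], NA)))
  print(round(x$scores[, 1:min(2, ncol(x$scores)), drop = FALSE], 3))
  invisible(x)
}
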