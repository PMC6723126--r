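#' Z-score expression profiles
#'
#' Row-standardizes a fold-change (or expression) matrix: each feature's
#' profile gets mean 0 and standard deviation 1, so clustering compares
#' shapes rather than amplitudes. Constant profiles cannot be standardized
#' and are excluded (reported separately).
#'
#' @param x Numeric matrix (features x conditions) or an `fc_profiles`
#'   object, in which case all log2 fold-change columns are used — including
#'   the control, whose zero fold-change anchors each profile at its
#'   pre-pulse baseline (so a transient induction reads as a rise from
#'   baseline, not as a decay across the post-pulse samples).
#' @return List of class `z_profiles`: `z` (standardized matrix), `constant`
#'   (ids of excluded constant profiles).
#' @export
zscore_profiles <- function(x) {
  if (inherits(x, "fc_profiles")) {
    conds <- design_conditions(x$design, x$layer)
    x <- x$log2fc[, conds$condition, drop = FALSE]
  }
  stopifnot(is.matrix(x), !anyNA(x))
  sds <- apply(x, 1, stats::sd)
  constant <- rownames(x)[sds == 0]
  keep <- sds > 0
  z <- (x[keep, , drop = FALSE] - rowMeans(x[keep, , drop = FALSE])) / sds[keep]
  structure(list(z = z, constant = constant), class = "z_profiles")
}

#' Extract tight expression clusters
#'
#' A data-extraction clustering: rather than partitioning every profile, it
#' keeps only coherent groups and leaves the rest unassigned. The procedure
#' over-clusters with seeded k-means (`k_init` centres), retains clusters
#' whose mean within-cluster distance to the centroid falls below the
#' `tightness_quantile` of the dispersion distribution, iteratively merges
#' retained clusters whose centroid Pearson correlation exceeds `merge_r`,
#' and finally drops clusters smaller than `min_size`. Members of dropped or
#' loose clusters become unassigned. The result is deterministic given
#' `seed`.
#'
#' @param z A [zscore_profiles()] result or a standardized matrix.
#' @param k_init Initial number of k-means centres (>= 2, <= features).
#' @param tightness_quantile Dispersion quantile below which a cluster is
#'   kept (0.5 keeps the tighter half).
#' @param merge_r Centroid correlation above which clusters merge.
#' @param min_size Minimum surviving cluster size.
#' @param seed RNG seed for k-means initialization.
#' @return List of class `cluster_set`: `clusters` (list of `id`, `members`,
#'   `mean_profile`, `shape`), `unassigned` (feature ids), `params`.
#' @export
extract_tight_clusters <- function(z, k_init = 30, tightness_quantile = 0.5,
                                   merge_r = 0.8, min_size = 5, seed = 1) {
  Z <- if (inherits(z, "z_profiles")) z$z else z
  stopifnot(is.matrix(Z), nrow(Z) >= 1)
  if (k_init < 2) stop("k_init must be >= 2")
  if (k_init > nrow(Z)) stop("k_init exceeds the number of features")
  n_distinct <- nrow(unique(Z))
  k <- min(k_init, n_distinct)
  set.seed(seed)
  km <- if (k >= 2) {
    stats::kmeans(Z, centers = k, nstart = 10, iter.max = 100)
  } else {
    list(cluster = rep(1L, nrow(Z)), centers = matrix(colMeans(Z), 1))
  }
  groups <- split(rownames(Z), km$cluster)
  # mean Euclidean distance of members to their centroid
  disp <- vapply(seq_along(groups), function(g) {
    rows <- Z[groups[[g]], , drop = FALSE]
    mean(sqrt(rowSums((rows - rep(km$centers[g, ], each = nrow(rows)))^2)))
  }, numeric(1))
  keep <- disp <= stats::quantile(disp, tightness_quantile)
  kept <- groups[keep]
  # iterative merge of the most correlated centroid pair
  if (length(kept) > 1) {
    repeat {
      cen <- t(vapply(kept, function(m) colMeans(Z[m, , drop = FALSE]),
                      numeric(ncol(Z))))
      if (nrow(cen) < 2) break
      cm <- suppressWarnings(stats::cor(t(cen)))
      diag(cm) <- -Inf
      cm[is.na(cm)] <- -Inf
      if (max(cm) <= merge_r) break
      ij <- which(cm == max(cm), arr.ind = TRUE)[1, ]
      kept[[ij[1]]] <- c(kept[[ij[1]]], kept[[ij[2]]])
      kept[[ij[2]]] <- NULL
    }
  }
  kept <- kept[vapply(kept, length, 0L) >= min_size]
  kept <- kept[order(-vapply(kept, length, 0L))]
  clusters <- lapply(seq_along(kept), function(i) {
    prof <- colMeans(Z[kept[[i]], , drop = FALSE])
    list(id = paste0("C", i), members = kept[[i]], mean_profile = prof,
         shape = classify_cluster_shape(prof))
  })
  assigned <- unlist(lapply(clusters, `[[`, "members"), use.names = FALSE)
  structure(list(clusters = clusters,
                 unassigned = setdiff(rownames(Z), assigned),
                 params = list(k_init = k_init,
                               tightness_quantile = tightness_quantile,
                               merge_r = merge_r, min_size = min_size,
                               seed = seed)),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d clusters, %d assigned, %d unassigned\n",
              length(x$clusters),
              sum(vapply(x$clusters, function(cl) length(cl$members), 0L)),
              length(x$unassigned)))
  for (cl in x$clusters)
    cat(sprintf("  %s: %d genes [%s]\n", cl$id, length(cl$members), cl$shape))
  invisible(x)
}

#' Classify the shape of a mean cluster profile
#'
#' Excursions are measured relative to the profile's first time point (the
#' state closest to the pre-pulse baseline). A profile is `up` when its
#' dominant excursion is positive and any opposite excursion stays below half
#' the dominant one; `down` is symmetric; `oscillatory` when a downward
#' excursion is followed by a later upward excursion, both exceeding half the
#' dominant magnitude (initial downregulation followed by late upregulation).
#'
#' @param profile Numeric vector (length >= 3), typically a mean Z-profile.
#' @return `"up"`, `"down"` or `"oscillatory"`.
#' @export
classify_cluster_shape <- function(profile) {
  stopifnot(is.numeric(profile), length(profile) >= 3)
  d <- profile - profile[1]
  M <- max(d); m <- min(d)
  A <- max(abs(d))
  if (A == 0) return("up")   # flat relative to start; degenerate
  i_min <- which.min(d); i_max <- which.max(d)
  if (m <= -0.5 * A && M >= 0.5 * A && i_min < i_max) return("oscillatory")
  if (abs(M) >= abs(m)) "up" else "down"
}

#' Summary statistics of a cluster set
#'
#' @param set A [extract_tight_clusters()] result.
#' @param n_total Total number of input features (regulated genes).
#' @return List: `n_clusters`, `n_clustered`, `fraction_clustered` (percent,
#'   one decimal), `mean_cluster_size` (one decimal).
#' @export
cluster_summary <- function(set, n_total) {
  stopifnot(inherits(set, "cluster_set"))
  sizes <- vapply(set$clusters, function(cl) length(cl$members), 0L)
  n_clustered <- sum(sizes)
  list(n_clusters = length(sizes),
       n_clustered = n_clustered,
       fraction_clustered = if (n_total > 0)
         .round_halfup(100 * n_clustered / n_total, 1) else 0,
       mean_cluster_size = if (length(sizes))
         .round_halfup(n_clustered / length(sizes), 1) else 0)
}
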