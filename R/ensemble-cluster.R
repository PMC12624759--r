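# Frame clustering on a coordinate selection, with Davies-Bouldin, pseudo-F
# (Calinski-Harabasz form) and explained-variance quality metrics, and
# representative-frame extraction for ensemble docking.

#' Per-frame coordinate features for clustering
#'
#' Every frame is superposed onto the first frame using the selection, then
#' the selected coordinates are flattened to one row per frame. Euclidean
#' distance between rows equals sqrt(n_selected) times the selection RMSD
#' under this single global superposition (the usual trajectory-clustering
#' convention; an approximation to true pairwise-fit RMSD).
#'
#' @param traj a `mol_trajectory`.
#' @param selection `atom_selection`/indices clustered on (e.g. loop backbone
#'   heavy atoms).
#' @return numeric matrix (n_frames x 3 n_selected) with attribute `n_sel`.
#' @export
frame_features <- function(traj, selection) {
  na <- n_atoms(traj)
  sel <- .resolve_indices(selection, na)
  if (length(sel) == 0) stop("empty selection for frame features")
  ref <- frame_coords(traj, 1)
  feats <- t(vapply(seq_len(n_frames(traj)), function(k) {
    fitted <- superpose(frame_coords(traj, k), ref, sel)$coords
    as.vector(t(fitted[sel, , drop = FALSE]))
  }, numeric(3 * length(sel))))
  attr(feats, "n_sel") <- length(sel)
  feats
}

.make_clustering_result <- function(features, labels, method) {
  labels <- as.integer(labels)
  k <- length(unique(labels))
  reps <- vapply(sort(unique(labels)), function(cl) {
    rows <- which(labels == cl)
    ctr <- colMeans(features[rows, , drop = FALSE])
    rows[which.min(rowSums(sweep(features[rows, , drop = FALSE], 2, ctr)^2))]
  }, integer(1))
  metrics <- cluster_metrics(features, labels)
  structure(list(labels = labels, k = k, representatives = reps,
                 metrics = metrics, method = method),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("<clustering_result> %s, k = %d; R2 = %.3f, DBI = %s, psF = %s\n",
              x$method, x$k, x$metrics$R2,
              if (is.na(x$metrics$DBI)) "NA" else sprintf("%.3f", x$metrics$DBI),
              if (is.na(x$metrics$psF)) "NA" else sprintf("%.1f", x$metrics$psF)))
  invisible(x)
}

#' K-means clustering of trajectory frames
#'
#' Multi-start k-means on the frame features; deterministic for a fixed seed.
#'
#' @param features matrix from [frame_features()].
#' @param k number of clusters (default 10).
#' @param n_init independent starts; the best by within-cluster sum of squares
#'   is kept (default 10).
#' @param seed RNG seed (default 1).
#' @return a `clustering_result`: `labels`, `k`, `representatives` (frame
#'   nearest each centroid) and `metrics` (DBI, psF, R2).
#' @export
kmeans_cluster <- function(features, k = 10, n_init = 10, seed = 1) {
  n <- nrow(features)
  if (k > n) stop("k (", k, ") exceeds the number of frames (", n, ")")
  if (k == n) {
    # every frame its own cluster: the unique zero-SSE optimum
    return(.make_clustering_result(features, seq_len(n), "kmeans"))
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  km <- suppressWarnings(
    kmeans(features, centers = k, nstart = n_init, iter.max = 200)
  )
  .make_clustering_result(features, km$cluster, "kmeans")
}

#' Average-linkage hierarchical clustering with an RMSD cutoff
#'
#' Agglomerates on the RMSD metric (feature distance / sqrt(n_selected)) and
#' cuts the tree where the merge distance exceeds the cutoff.
#'
#' @param features matrix from [frame_features()] (attribute `n_sel` used to
#'   convert feature distance to RMSD; pass `n_sel` explicitly for bare
#'   matrices).
#' @param rmsd_cutoff Angstrom (default 2.5).
#' @param n_sel selection size, overriding the attribute.
#' @return a `clustering_result`.
#' @export
hierarchical_cluster <- function(features, rmsd_cutoff = 2.5, n_sel = NULL) {
  if (nrow(features) < 2) stop("need at least 2 frames")
  ns <- if (!is.null(n_sel)) n_sel else attr(features, "n_sel")
  if (is.null(ns)) ns <- ncol(features) / 3
  d <- dist(features) / sqrt(ns)
  hc <- hclust(d, method = "average")
  labels <- cutree(hc, h = rmsd_cutoff)
  .make_clustering_result(features, labels, "hierarchical-average")
}

#' Clustering quality metrics
#'
#' Davies-Bouldin index (lower is better), pseudo-F in the Calinski-Harabasz
#' form (higher is better) and R-squared, the fraction of coordinate variance
#' explained by the clustering.
#'
#' @param features feature matrix (n x p).
#' @param labels integer cluster labels covering all rows.
#' @return list with `DBI`, `psF`, `R2`. DBI and psF are NA (with a warning)
#'   for fewer than 2 clusters; R2 is always returned.
#' @export
cluster_metrics <- function(features, labels) {
  labels <- as.integer(factor(labels))
  n <- nrow(features)
  k <- length(unique(labels))
  gmean <- colMeans(features)
  sst <- sum(sweep(features, 2, gmean)^2)
  centroids <- t(vapply(seq_len(k), function(cl) {
    colMeans(features[labels == cl, , drop = FALSE])
  }, numeric(ncol(features))))
  sse <- sum(vapply(seq_len(k), function(cl) {
    sum(sweep(features[labels == cl, , drop = FALSE], 2, centroids[cl, ])^2)
  }, numeric(1)))
  r2 <- if (sst > 0) 1 - sse / sst else 1
  if (k < 2) {
    warning("DBI and pseudo-F undefined for k < 2")
    return(list(DBI = NA_real_, psF = NA_real_, R2 = r2))
  }
  # within-cluster scatter: mean distance to centroid
  s <- vapply(seq_len(k), function(cl) {
    rows <- which(labels == cl)
    mean(sqrt(rowSums(sweep(features[rows, , drop = FALSE], 2, centroids[cl, ])^2)))
  }, numeric(1))
  dbi <- mean(vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i), function(j) {
      (s[i] + s[j]) / sqrt(sum((centroids[i, ] - centroids[j, ])^2))
    }, numeric(1)))
  }, numeric(1)))
  psf <- if (n > k && sse > 0) ((sst - sse) / (k - 1)) / (sse / (n - k)) else Inf
  list(DBI = dbi, psF = psf, R2 = r2)
}
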