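# Exploratory structure discovery on the TIS matrix: hierarchical clustering
# with linkage selection by agglomerative coefficient, and PCA.

# Accept either a tis_matrix (channels x samples) or a plain samples x
# features matrix; always return samples x features with rownames.
.sample_matrix <- function(x) {
  if (inherits(x, "tis_matrix")) t(x$D) else as.matrix(x)
}

.hclust_method <- function(method) {
  method <- match.arg(method, c("ward", "average", "single", "complete"))
  c(ward = "ward.D2", average = "average", single = "single",
    complete = "complete")[[method]]
}

#' Agglomerative coefficient of a linkage method
#'
#' For each sample, let `m(i)` be the height at which it is first merged into
#' a cluster divided by the height of the final merge; the agglomerative
#' coefficient is `mean(1 - m(i))`. Values near 1 indicate strong clustering
#' structure, so the linkage with the largest coefficient is the one to use.
#' Ward linkage is computed in the squared-distance (Ward.D2) convention.
#'
#' @param x A `tis_matrix` or a samples x features matrix.
#' @param method One of `"ward"`, `"average"`, `"single"`, `"complete"`.
#' @param metric Distance metric passed to [stats::dist()].
#' @return Scalar in `[0, 1]`.
#' @export
agglomerative_coefficient <- function(x, method = "ward",
                                      metric = "euclidean") {
  m <- .sample_matrix(x)
  if (nrow(m) < 3L)
    stop("need at least 3 samples for an agglomerative coefficient")
  hc <- stats::hclust(stats::dist(m, method = metric),
                      method = .hclust_method(method))
  first_height <- numeric(nrow(m))
  for (k in seq_len(nrow(hc$merge))) {
    leaves <- -hc$merge[k, ][hc$merge[k, ] < 0]
    first_height[leaves] <- hc$height[k]
  }
  mean(1 - first_height / hc$height[length(hc$height)])
}

#' Hierarchical cluster analysis of the TIS matrix
#'
#' Agglomerative clustering of samples (default: Ward linkage on Euclidean
#' distances, the combination that maximizes the agglomerative coefficient on
#' wax TIS data), with the merge tree, heights and the coefficient.
#'
#' @inheritParams agglomerative_coefficient
#' @return An object of class `hca_result`: `hclust` (the [stats::hclust()]
#'   tree), `merges` (data frame cluster1, cluster2, height), `labels`,
#'   `linkage_method`, `agglomerative_coefficient`.
#' @export
run_hca <- function(x, method = "ward", metric = "euclidean") {
  m <- .sample_matrix(x)
  if (nrow(m) < 2L) stop("need at least 2 samples")
  if (!all(is.finite(m))) stop("non-finite values in the data matrix")
  hc <- stats::hclust(stats::dist(m, method = metric),
                      method = .hclust_method(method))
  ac <- if (nrow(m) >= 3L) agglomerative_coefficient(x, method, metric)
        else NA_real_
  structure(list(
    hclust = hc,
    merges = data.frame(cluster1 = hc$merge[, 1], cluster2 = hc$merge[, 2],
                        height = hc$height),
    labels = hc$labels, linkage_method = method,
    agglomerative_coefficient = ac),
    class = "hca_result")
}

#' @export
print.hca_result <- function(x, ...) {
  cat(sprintf("<hca_result> %d samples, %s linkage, AC = %.3f\n",
              length(x$labels), x$linkage_method,
              x$agglomerative_coefficient))
  invisible(x)
}

#' Cut an HCA tree into k clusters
#'
#' @param hca An `hca_result`.
#' @param k Number of clusters.
#' @return Integer cluster assignment named by sample.
#' @export
cut_hca <- function(hca, k) {
  stopifnot(inherits(hca, "hca_result"))
  stats::cutree(hca$hclust, k = k)
}

#' Export a dendrogram as Newick text
#'
#' Writes the merge tree in Newick format (readable by any tree viewer) and,
#' optionally, the merge table as CSV.
#'
#' @param hca An `hca_result`.
#' @param path Newick output path.
#' @param merges_path Optional CSV path for the merge table.
#' @return `path`, invisibly.
#' @export
export_dendrogram <- function(hca, path, merges_path = NULL) {
  stopifnot(inherits(hca, "hca_result"))
  ape::write.tree(ape::as.phylo(hca$hclust), file = path)
  if (!is.null(merges_path))
    utils::write.csv(hca$merges, merges_path, row.names = FALSE)
  invisible(path)
}

#' Principal component analysis of the TIS matrix
#'
#' PCA on samples-as-observations. Preprocessing is mean-centering only by
#' default: the columns are already base-peak normalized to a common 0-1
#' scale, and leaving the variance structure intact keeps the loadings
#' concentrated on the dominant ions. Component signs are fixed so that the
#' largest-magnitude loading of each component is positive, making the output
#' deterministic.
#'
#' @param x A `tis_matrix` or a samples x features matrix.
#' @param n_components Number of components to keep (default: all).
#' @param scale. Also divide channels by their s.d. (off by default).
#' @return An object of class `pca_result`: `scores` (samples x components),
#'   `loadings` (channels x components), `explained_variance_fraction`.
#' @export
run_pca <- function(x, n_components = NULL, scale. = FALSE) {
  m <- .sample_matrix(x)
  if (nrow(m) < 2L) stop("need at least 2 samples")
  max_comp <- min(nrow(m) - 1L, ncol(m))
  if (is.null(n_components)) n_components <- max_comp
  if (n_components > max_comp)
    stop(sprintf("n_components must be <= %d", max_comp))
  if (scale.) {
    keep_sd <- apply(m, 2, stats::sd) > 0
    pc <- stats::prcomp(m[, keep_sd, drop = FALSE], center = TRUE,
                        scale. = TRUE)
    load_full <- matrix(0, ncol(m), ncol(pc$rotation),
                        dimnames = list(colnames(m), colnames(pc$rotation)))
    load_full[keep_sd, ] <- pc$rotation
    pc$rotation <- load_full
  } else {
    pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  }
  k <- seq_len(n_components)
  scores <- pc$x[, k, drop = FALSE]
  loadings <- pc$rotation[, k, drop = FALSE]
  # deterministic sign convention
  for (j in seq_len(ncol(loadings))) {
    if (loadings[which.max(abs(loadings[, j])), j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(
    scores = scores, loadings = loadings,
    explained_variance_fraction = (pc$sdev^2 / sum(pc$sdev^2))[k]),
    class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  ev <- 100 * x$explained_variance_fraction
  cat(sprintf("<pca_result> %d components; explained variance: %s\n",
              ncol(x$scores),
              paste(sprintf("%.1f%%", ev[seq_len(min(3, length(ev)))]),
                    collapse = ", ")))
  invisible(x)
}
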