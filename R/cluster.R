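#' Principal component analysis of log expression
#'
#' Samples are the observations, genes the features.  The gene-wise means are
#' subtracted and components come from the singular value decomposition of
#' the centered matrix; the sign of each component is fixed so that its
#' largest-magnitude loading is positive, making results deterministic.
#'
#' @param log_expression Matrix of log expression, genes x samples (e.g. the
#'   `$log2` slot of [normalize_counts()]).
#' @param n_components Number of components (default: all available).
#' @return An object of class \code{"pca_result"}: `scores` (samples x k),
#'   `loadings` (genes x k), `explained_variance_fraction` (length k,
#'   non-increasing, summing to <= 1) and `sdev`.
#' @export
pca_expression <- function(log_expression,
                           n_components = min(dim(log_expression)) - 1L) {
  n <- ncol(log_expression)
  if (n < 2L) stop("need >= 2 samples")
  max_k <- min(nrow(log_expression), n)
  if (n_components < 1L || n_components > max_k) {
    stop("n_components must be in [1, ", max_k, "]")
  }
  x <- t(log_expression - rowMeans(log_expression))  # samples x genes, centered
  sv <- svd(x, nu = n_components, nv = n_components)
  sdev <- sv$d / sqrt(n - 1L)
  total_var <- sum(sdev^2)
  loadings <- sv$v
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  # sign convention: each loading vector's largest-|entry| is positive
  for (k in seq_len(n_components)) {
    i <- which.max(abs(loadings[, k]))
    if (loadings[i, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  dimnames(scores) <- list(colnames(log_expression),
                           paste0("PC", seq_len(n_components)))
  dimnames(loadings) <- list(rownames(log_expression),
                             paste0("PC", seq_len(n_components)))
  structure(list(scores = scores, loadings = loadings,
                 explained_variance_fraction =
                   sdev[seq_len(n_components)]^2 / total_var,
                 sdev = sdev[seq_len(n_components)]),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("PCA: %d samples x %d components\n", nrow(x$scores), ncol(x$scores)))
  evf <- round(100 * x$explained_variance_fraction, 1L)
  cat("  variance explained (%):", paste(evf, collapse = ", "), "\n")
  invisible(x)
}

#' Average-linkage hierarchical clustering on Euclidean distances
#'
#' Agglomerative UPGMA (unweighted average linkage) over Euclidean distances
#' between samples (columns) or genes (rows).
#'
#' @param mat Numeric matrix (genes x samples), all values finite.
#' @param axis Cluster `"samples"` (columns, default) or `"genes"` (rows).
#' @return A [stats::hclust] object (merge history, non-decreasing heights,
#'   leaf labels).
#' @export
hierarchical_cluster <- function(mat, axis = c("samples", "genes")) {
  axis <- match.arg(axis)
  if (any(!is.finite(mat))) stop("matrix contains non-finite values")
  x <- if (axis == "samples") t(mat) else mat
  if (nrow(x) < 2L) stop("need >= 2 items to cluster")
  stats::hclust(stats::dist(x, method = "euclidean"), method = "average")
}

#' Cut a dendrogram into k clusters
#'
#' @param dendrogram A [stats::hclust] object.
#' @param k Number of clusters, 1 <= k <= number of leaves.
#' @return Integer cluster labels named by leaf, in leaf order.
#' @export
cut_tree <- function(dendrogram, k) {
  n <- length(dendrogram$labels)
  if (k < 1L || k > n) stop("k must be in [1, ", n, "]")
  stats::cutree(dendrogram, k = k)
}

#' Export a dendrogram as a Newick string or file
#'
#' Branch lengths encode the merge heights (ultrametric tree).
#'
#' @param dendrogram A [stats::hclust] object.
#' @param path Optional output file; if NULL the Newick string is returned.
#' @return The Newick string (invisibly when written to `path`).
#' @export
export_newick <- function(dendrogram, path = NULL) {
  phy <- ape::as.phylo(dendrogram)
  if (is.null(path)) {
    ape::write.tree(phy)
  } else {
    ape::write.tree(phy, file = path)
    invisible(ape::write.tree(phy))
  }
}

#' Row-standardize a matrix (gene-wise z-scores)
#'
#' Subtracts each row's mean and divides by its population standard deviation
#' (divide-by-n; set `sd_type = "sample"` for the n-1 convention).
#' Zero-variance rows map to all-zero rows with a warning.
#'
#' @param mat Numeric matrix (genes x samples).
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return Matrix of the same shape.
#' @export
row_standardize <- function(mat, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  n <- ncol(mat)
  ctr <- mat - rowMeans(mat)
  denom <- if (sd_type == "population") n else n - 1L
  s <- sqrt(rowSums(ctr^2) / denom)
  zero <- s == 0 | !is.finite(s)
  if (any(zero)) {
    warning(sum(zero), " zero-variance row(s) mapped to zeros")
    s[zero] <- 1
  }
  out <- ctr / s
  out[zero, ] <- 0
  out
}
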