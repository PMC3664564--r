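# Unsupervised structure checks: average-linkage clustering of samples on
# correlation similarity, PCA on z-score-normalized expression, and a
# phenotype-separation (misassignment) score.

#' Z-score rows of a matrix (population standard deviation)
#'
#' Each row is centred to mean 0 and scaled to sd 1, using the population
#' (divide-by-n) standard deviation so the transform is a deterministic
#' function of the row values alone.
#'
#' @param x numeric matrix.
#' @return matrix of the same shape.
#' @export
#' @examples
#' zscore_rows(matrix(c(2, 4, 6), 1))  # -1.2247, 0, 1.2247
zscore_rows <- function(x) {
  mu <- rowMeans(x)
  cx <- x - mu
  sd_pop <- sqrt(rowMeans(cx^2))
  if (any(sd_pop == 0))
    warning("zero-variance row(s) cannot be z-scored")
  cx / sd_pop
}

#' Average-linkage clustering of samples on correlation similarity
#'
#' Samples are clustered agglomeratively with unweighted average linkage
#' (UPGMA) on the dissimilarity 1 - r, where r is the Pearson correlation
#' of the samples' log2 expression profiles over the chosen feature
#' subset. Samples are ordered by id before clustering so that ties break
#' deterministically.
#'
#' @param dataset an [expression_dataset].
#' @param feature_subset feature ids to cluster on (default: all).
#' @param log2 correlate log2-transformed values (default TRUE).
#' @return an object of class `hclust`.
#' @export
cluster_samples <- function(dataset, feature_subset = NULL, log2 = TRUE) {
  x <- dataset$values
  if (!is.null(feature_subset)) {
    miss <- setdiff(feature_subset, rownames(x))
    if (length(miss)) stop("unknown feature id(s): ",
                           paste(miss, collapse = ", "))
    x <- x[feature_subset, , drop = FALSE]
  }
  if (nrow(x) < 2) stop("need at least 2 features to correlate samples")
  if (ncol(x) < 2) stop("need at least 2 samples")
  if (log2) x <- base::log2(x)
  x <- x[, order(colnames(x)), drop = FALSE]
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance sample profile(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  r <- stats::cor(x)
  stats::hclust(stats::as.dist(1 - r), method = "average")
}

#' Export a sample dendrogram as a Newick string
#'
#' @param hc an `hclust` object (e.g. from [cluster_samples()]).
#' @return single Newick string with branch lengths derived from merge
#'   heights.
#' @export
dendrogram_newick <- function(hc) {
  ape::write.tree(ape::as.phylo(hc))
}

#' PCA of samples on z-score-normalized expression
#'
#' Each feature (row) is z-scored across samples (population sd); the
#' sample-space singular value decomposition of the standardized matrix
#' gives per-sample component scores and per-feature loadings. Each
#' component is oriented so that its largest-magnitude loading is positive.
#' Zero-variance features are dropped with a warning.
#'
#' @param dataset an [expression_dataset].
#' @param feature_subset feature ids to use (default: all).
#' @param log2 z-score log2-transformed values (default TRUE).
#' @return list of class `pca_result` with `scores` (samples x components,
#'   columns `PC1`, `PC2`, ...), `loadings` (features x components),
#'   `explained_variance` (fractions, non-increasing), `z` (the
#'   standardized matrix).
#' @export
pca_samples <- function(dataset, feature_subset = NULL, log2 = TRUE) {
  x <- dataset$values
  if (!is.null(feature_subset)) {
    miss <- setdiff(feature_subset, rownames(x))
    if (length(miss)) stop("unknown feature id(s): ",
                           paste(miss, collapse = ", "))
    x <- x[feature_subset, , drop = FALSE]
  }
  if (log2) x <- base::log2(x)
  mu <- rowMeans(x)
  sd_pop <- sqrt(rowMeans((x - mu)^2))
  if (any(sd_pop == 0)) {
    warning(sum(sd_pop == 0), " zero-variance feature(s) dropped")
    x <- x[sd_pop > 0, , drop = FALSE]
  }
  if (nrow(x) < 2) stop("need at least 2 features with nonzero variance")
  z <- zscore_rows(x)
  sv <- svd(z)
  ncomp <- sum(sv$d > max(sv$d) * 1e-12)
  d <- sv$d[seq_len(ncomp)]
  u <- sv$u[, seq_len(ncomp), drop = FALSE]
  v <- sv$v[, seq_len(ncomp), drop = FALSE]
  # orient: largest-|loading| entry positive per component
  for (k in seq_len(ncomp)) {
    i <- which.max(abs(u[, k]))
    if (u[i, k] < 0) {
      u[, k] <- -u[, k]
      v[, k] <- -v[, k]
    }
  }
  scores <- v %*% diag(d, ncomp)
  dimnames(scores) <- list(colnames(z), paste0("PC", seq_len(ncomp)))
  dimnames(u) <- list(rownames(z), paste0("PC", seq_len(ncomp)))
  structure(list(scores = scores, loadings = u,
                 explained_variance = d^2 / sum(sv$d^2), z = z),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  ev <- x$explained_variance
  cat(sprintf("pca_result: %d samples, %d components; PC1 %.1f%%, PC2 %.1f%%\n",
              nrow(x$scores), length(ev), 100 * ev[1],
              if (length(ev) > 1) 100 * ev[2] else NA))
  invisible(x)
}

#' Phenotype-separation score (misassignment count)
#'
#' Quantifies how well a 2-group phenotype is recovered by either a
#' 2-cluster partition (minimal mismatches over the two possible
#' cluster-to-label mappings) or a 1-d score such as PC1 (minimal
#' misclassifications over every threshold and both orientations).
#'
#' @param labels factor-like with exactly two levels (e.g. case/control).
#' @param x either a cluster assignment of the same length (two distinct
#'   values) or a numeric score vector.
#' @return integer misassignment count (0 = perfect separation).
#' @export
separation_score <- function(labels, x) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop("labels must have exactly two levels")
  if (length(labels) != length(x)) stop("length mismatch")
  y <- as.integer(labels) - 1L
  if (is.numeric(x) && length(unique(x)) > 2) {
    o <- order(x)
    ys <- y[o]
    n <- length(ys)
    # threshold after position t (0..n): left side predicted 0 or 1
    best <- n
    for (t in 0:n) {
      pred <- c(rep(0L, t), rep(1L, n - t))
      best <- min(best, sum(pred != ys), sum((1L - pred) != ys))
    }
    best
  } else {
    a <- as.integer(as.factor(x)) - 1L
    min(sum(a != y), sum((1L - a) != y))
  }
}

#' Two-cluster sample partition from a dendrogram
#'
#' @param hc `hclust` from [cluster_samples()].
#' @return named integer vector of cluster memberships (1 or 2).
#' @export
cut_two <- function(hc) stats::cutree(hc, k = 2)
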