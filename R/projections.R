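#' Principal component analysis of a feature matrix
#'
#' Thin wrapper around [stats::prcomp()] returning the pieces the pipeline
#' uses: orthonormal components, explained-variance fractions, and
#' per-position coordinates (scores).
#'
#' @param matrix A `feature_matrix` or numeric matrix (rows = positions).
#' @return List with `rotation` (feature x component loadings),
#'   `explained` (fractions summing to 1, non-increasing), `coordinates`
#'   (position x component scores), and `center`.
#' @export
pca_fit <- function(matrix) {
  m <- if (inherits(matrix, "feature_matrix")) matrix$values else
    as.matrix(matrix)
  if (nrow(m) < 2L) stop("need at least 2 rows for PCA")
  p <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  list(rotation = p$rotation,
       explained = p$sdev^2 / sum(p$sdev^2),
       coordinates = p$x,
       center = p$center)
}

# Fraction of each point's n nearest neighbors (Euclidean, 2D) sharing its
# label, averaged over points. Distance ties are broken by point index.
knn_label_score <- function(xy, labels, n_neighbors) {
  n <- nrow(xy)
  stopifnot(n >= n_neighbors + 1L)
  d <- as.matrix(stats::dist(xy))
  same <- vapply(seq_len(n), function(i) {
    ord <- order(d[i, ], seq_len(n))
    ord <- ord[ord != i][seq_len(n_neighbors)]
    mean(labels[ord] == labels[i])
  }, numeric(1))
  mean(same)
}

#' Rank 2D principal-component projections by class separation
#'
#' Scores every pair of principal components by the mean fraction of each
#' point's nearest neighbors (default 10, Euclidean distance within the 2D
#' projection) that share the point's class label, and ranks pairs by that
#' score. A perfectly separated pair scores 1; chance level for balanced
#' two-class data is about 0.5. Ties are broken by lexicographic component
#' order, and equal-distance neighbor ties by point index, so the ranking
#' is deterministic.
#'
#' @param coordinates Position x component score matrix (e.g.
#'   `pca_fit()$coordinates`).
#' @param labels Class label per row.
#' @param n_neighbors Neighbors per point (default 10).
#' @param max_components Restrict to the first `max_components` components
#'   (default all).
#' @return Data frame with columns `pc_i`, `pc_j`, `score`, sorted by
#'   decreasing score then `(pc_i, pc_j)`.
#' @export
informative_projections <- function(coordinates, labels, n_neighbors = 10L,
                                    max_components = NULL) {
  m <- as.matrix(coordinates)
  stopifnot(nrow(m) == length(labels), nrow(m) >= n_neighbors + 1L)
  nc <- if (is.null(max_components)) ncol(m) else min(max_components, ncol(m))
  pairs <- utils::combn(nc, 2L)
  scores <- apply(pairs, 2L, function(ij) {
    knn_label_score(m[, ij, drop = FALSE], labels, n_neighbors)
  })
  out <- data.frame(pc_i = pairs[1, ], pc_j = pairs[2, ], score = scores)
  out[order(-out$score, out$pc_i, out$pc_j), , drop = FALSE]
}

#' Fisher linear discriminant analysis for two classes
#'
#' Computes the closed-form Fisher discriminant direction
#' `w = Sw^-1 (mu_S - mu_U)` (pooled within-class scatter `Sw`,
#' ridge-regularized by `lambda * trace(Sw)/d` when near-singular), projects
#' every position onto it, and standardizes the 1D scores to unit pooled
#' within-class variance so that the class mean difference is comparable
#' across window sizes. For two classes the reduction is one-dimensional.
#'
#' @param matrix A `feature_matrix` or numeric matrix.
#' @param labels Two-level class label per row (`"U"`/`"S"` or any two
#'   values).
#' @param lambda Relative ridge added to `Sw` when its reciprocal condition
#'   number falls below `1e-10` (default `1e-6`).
#' @return An object of class `lda_result`: list with `direction` (unit
#'   vector over features), `eigenvector` (per-feature loadings of the
#'   standardized discriminant), `scores` (standardized per-position 1D
#'   values), `class_mean_difference` (non-negative), and `class_means`.
#' @export
lda_fit <- function(matrix, labels, lambda = 1e-6) {
  m <- if (inherits(matrix, "feature_matrix")) matrix$values else
    as.matrix(matrix)
  labels <- as.character(labels)
  lv <- unique(labels)
  if (length(lv) != 2L) stop("lda_fit needs exactly two classes, got ",
                             length(lv))
  lv <- sort(lv)
  x0 <- m[labels == lv[1], , drop = FALSE]
  x1 <- m[labels == lv[2], , drop = FALSE]
  if (nrow(x0) < 2L || nrow(x1) < 2L) stop("each class needs >= 2 rows")
  sw <- crossprod(sweep(x0, 2L, colMeans(x0))) +
        crossprod(sweep(x1, 2L, colMeans(x1)))
  sw <- sw / (nrow(m) - 2L)
  d <- ncol(m)
  if (rcond(sw) < 1e-10) {
    sw <- sw + diag(lambda * sum(diag(sw)) / d, d)
  }
  w <- solve(sw, colMeans(x1) - colMeans(x0))
  w <- w / sqrt(sum(w^2))
  scores <- drop(m %*% w)
  s0 <- scores[labels == lv[1]]
  s1 <- scores[labels == lv[2]]
  pooled_var <- ((length(s0) - 1) * stats::var(s0) +
                 (length(s1) - 1) * stats::var(s1)) / (length(scores) - 2)
  scale_factor <- sqrt(pooled_var)
  if (scale_factor > 0) {
    scores <- scores / scale_factor
    eigenvector <- w / scale_factor
  } else {
    eigenvector <- w
  }
  cm <- c(mean(scores[labels == lv[1]]), mean(scores[labels == lv[2]]))
  names(cm) <- lv
  structure(list(direction = w, eigenvector = eigenvector, scores = scores,
                 class_mean_difference = abs(diff(cm)), class_means = cm,
                 classes = lv),
            class = "lda_result")
}

#' @export
print.lda_result <- function(x, ...) {
  cat("Fisher LDA: classes ", paste(x$classes, collapse = "/"),
      ", standardized class mean difference ",
      format(x$class_mean_difference, digits = 4), "\n", sep = "")
  invisible(x)
}
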