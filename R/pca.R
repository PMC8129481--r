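#' Principal-component scores of samples
#'
#' Samples are the observations: the proteins-by-samples matrix of log2
#' intensities is transposed, each protein (column) is mean-centered (no
#' variance scaling — the proteomics convention, so abundant proteins keep
#' their weight), and the scores come from the singular-value decomposition.
#' For reproducibility the sign of each component is fixed so that its
#' largest-magnitude protein loading is positive.
#'
#' @param x numeric proteins-by-samples matrix of log2 intensities with no
#'   missing cells, or an imputed [intensity_matrix()] (intensities are then
#'   log2-transformed internally).
#' @param k number of components to return (`<= min(n_samples, n_proteins)`).
#' @return list of class `pca_scores`: `scores` (data.frame, `sample_id` +
#'   `PC1..PCk`), `explained_variance` (fraction per returned component) and
#'   `loadings`.
#' @export
pca_scores <- function(x, k = 2) {
  if (inherits(x, "intensity_matrix")) {
    if (anyNA(x$intensities)) stop_("impute before PCA")
    x <- log2(x$intensities)
  }
  if (!is.matrix(x) || !is.numeric(x)) stop_("`x` must be a numeric matrix")
  if (anyNA(x)) stop_("`x` must have no missing cells")
  if (ncol(x) < 2L) stop_("PCA needs >= 2 samples")
  k <- assert_count(k, "k")
  if (k > min(dim(x))) {
    stop_("k = %d exceeds min(dim) = %d", k, min(dim(x)))
  }
  xs <- t(x)                               # samples x proteins
  xs <- scale(xs, center = TRUE, scale = FALSE)
  sv <- svd(xs)
  for (j in seq_len(k)) {
    i0 <- which.max(abs(sv$v[, j]))
    if (sv$v[i0, j] < 0) {
      sv$v[, j] <- -sv$v[, j]
      sv$u[, j] <- -sv$u[, j]
    }
  }
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], nrow = k)
  colnames(scores) <- sprintf("PC%d", seq_len(k))
  ev <- sv$d^2 / sum(sv$d^2)
  structure(
    list(
      scores = data.frame(sample_id = colnames(x), scores,
                          stringsAsFactors = FALSE),
      explained_variance = ev[seq_len(k)],
      loadings = sv$v[, seq_len(k), drop = FALSE]
    ),
    class = "pca_scores"
  )
}

#' @export
print.pca_scores <- function(x, ...) {
  cat(sprintf("<pca_scores> %d samples, %d components (%.1f%% variance)\n",
              nrow(x$scores), length(x$explained_variance),
              100 * sum(x$explained_variance)))
  invisible(x)
}
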