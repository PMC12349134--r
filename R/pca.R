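#' PCA baseline for the embedding comparison
#'
#' Fits a rank-`n_components` principal component model on the training split
#' (exact singular value decomposition; the `seed` is stored for provenance
#' and for parity with randomized solvers). Reconstruction is projection onto
#' the retained basis followed by back-projection.
#'
#' @param table A curated [phenome_table()].
#' @param split A [stratified_split()] assignment.
#' @param n_components Number of principal components; must not exceed either
#'   training-data dimension.
#' @param seed Stored provenance seed.
#' @return An object of class `pca_baseline`: centering vector, orthonormal
#'   basis (`rotation`), all training covariance eigenvalues, and settings.
#' @export
fit_pca_baseline <- function(table, split, n_components = 100, seed = 1L) {
  stopifnot(inherits(table, "phenome_table"))
  train_idx <- which(split == "train")
  if (!length(train_idx)) fail("empty train split")
  X <- table$values[train_idx, , drop = FALSE]
  if (anyNA(X)) fail("table contains missing values; curate it first")
  if (n_components > min(dim(X))) {
    fail("n_components (%d) exceeds min training dimension (%d)",
         n_components, min(dim(X)))
  }
  center <- colMeans(X)
  sv <- svd(sweep(X, 2, center), nu = 0)
  eigenvalues <- sv$d^2 / (nrow(X) - 1)
  structure(list(
    center = center,
    rotation = sv$v[, seq_len(n_components), drop = FALSE],
    eigenvalues = eigenvalues,
    n_components = n_components,
    n_train = nrow(X),
    seed = as.integer(seed)
  ), class = "pca_baseline")
}

#' @exportS3Method base::print
print.pca_baseline <- function(x, ...) {
  cat(sprintf("<pca_baseline> %d components over %d variables (train n=%d)\n",
              x$n_components, nrow(x$rotation), x$n_train))
  invisible(x)
}

reconstruct_pca <- function(model, x) {
  scores <- sweep(as.matrix(x), 2, model$center) %*% model$rotation
  sweep(scores %*% t(model$rotation), 2, model$center, `+`)
}

#' @export
mse_test.pca_baseline <- function(model, table, split, subset = "test") {
  idx <- which(split == subset)
  if (!length(idx)) fail("empty '%s' split", subset)
  X <- table$values[idx, , drop = FALSE]
  mean(rowSums((reconstruct_pca(model, X) - X)^2))
}
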