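#' Fit a principal-component model
#'
#' Eigendecomposition of the sample covariance matrix of the mean-centred
#' feature columns. Eigenvalues are sorted in descending order and tiny
#' negative values arising from floating point are clipped to zero;
#' eigenvector signs are fixed so each component's largest-magnitude
#' loading is positive, making the decomposition fully deterministic.
#'
#' @param x Feature matrix or tibble with at least 2 rows.
#' @return A `pca_model`: `center` (column means), `values` (eigenvalues),
#'   `vectors` (orthonormal loading matrix, one column per component),
#'   `explained` (variance ratios summing to 1).
#' @examples
#' m <- fit_pca(matrix(rnorm(40), 20))
#' sum(m$explained)
#' @export
fit_pca <- function(x) {
  x <- feature_block(x)
  if (nrow(x) < 2) abort("PCA needs at least 2 rows")
  ctr <- colMeans(x)
  S <- cov(x)
  if (all(abs(S) < 1e-300)) abort("cannot fit PCA on constant-only data")
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  vecs <- e$vectors
  for (j in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  rownames(vecs) <- colnames(x)
  structure(list(center = ctr, values = vals, vectors = vecs,
                 explained = vals / sum(vals)),
            class = "pca_model")
}

#' Project rows onto the leading principal components
#'
#' Centres `x` with the model's training means and multiplies by the top
#' `k` eigenvectors. With `k` equal to the full rank the projection is an
#' isometry and [pca_reconstruct()] recovers the input to floating-point
#' accuracy.
#'
#' @param model A [fit_pca()] model.
#' @param x Rows to project (training or held-out).
#' @param k Number of components, `1 <= k <= ncol(model$vectors)`.
#' @return Numeric matrix `n x k` with columns `PC1..PCk`.
#' @export
project_pca <- function(model, x, k = choose_k(model)) {
  x <- feature_block(x)
  if (k < 1 || k > ncol(model$vectors)) {
    abort(sprintf("k = %d out of range 1..%d", k, ncol(model$vectors)))
  }
  sc <- sweep(x, 2, model$center) %*% model$vectors[, seq_len(k), drop = FALSE]
  colnames(sc) <- paste0("PC", seq_len(k))
  sc
}

#' @rdname project_pca
#' @param scores Matrix of projected rows as returned by [project_pca()].
#' @export
pca_reconstruct <- function(model, scores) {
  k <- ncol(scores)
  sweep(scores %*% t(model$vectors[, seq_len(k), drop = FALSE]), 2,
        model$center, "+")
}

#' Choose the retained rank by cumulative explained variance
#'
#' Smallest `k` whose leading components explain at least
#' `variance_threshold` of the total variance (the projection rank is not
#' prescribed by the recognition design, so the package defaults to 95%).
#'
#' @param model A [fit_pca()] model.
#' @param variance_threshold Fraction in `(0, 1]`.
#' @return Integer rank.
#' @export
choose_k <- function(model, variance_threshold = 0.95) {
  stopifnot(variance_threshold > 0, variance_threshold <= 1)
  ratios <- model$explained
  which(cumsum(ratios) >= variance_threshold - 1e-12)[1]
}

#' @export
print.pca_model <- function(x, ...) {
  k95 <- choose_k(x)
  cat(sprintf("<pca_model: %d components; %d explain >= 95%% of variance>\n",
              length(x$values), k95))
  invisible(x)
}

#' @export
tidy.pca_model <- function(x, ...) {
  tibble::tibble(component = seq_along(x$values),
                 eigenvalue = x$values,
                 explained = x$explained,
                 cumulative = cumsum(x$explained))
}

#' @export
glance.pca_model <- function(x, ...) {
  tibble::tibble(n_components = length(x$values),
                 k_95 = choose_k(x),
                 total_variance = sum(x$values))
}

#' @export
autoplot.pca_model <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$explained)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$cumulative), colour = "red3") +
    ggplot2::geom_point(ggplot2::aes(y = .data$cumulative), colour = "red3") +
    ggplot2::labs(x = "principal component",
                  y = "explained variance ratio (bars) / cumulative (line)") +
    ggplot2::theme_minimal()
}
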