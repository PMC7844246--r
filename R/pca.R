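# Linear PCA with a variance-retention rule: keep the smallest number of
# leading components whose cumulative variance share reaches the requested
# fraction. Fitting is unsupervised by construction — class labels are not
# an argument — so dimensionality reduction happens before any involvement
# of the ground truth.

#' Fit a PCA projector with a variance-retention rule
#'
#' Centers the feature matrix, computes principal components (via
#' [stats::prcomp()]), and keeps the smallest `k` whose leading-`k` variance
#' share is at least `retain_fraction`.
#'
#' @param x numeric feature matrix (rows = examples).
#' @param retain_fraction fraction of total variance to retain, in (0, 1].
#' @return object of class `pca_projector`: `center`, `rotation`
#'   (`p x k`), `variances` (all component variances), `k`,
#'   `retained_fraction` (achieved), `p` (input dimension).
#' @examples
#' x <- matrix(rnorm(200), 50)
#' pr <- fit_pca(x, 0.9)
#' dim(predict(pr, x))
#' @export
fit_pca <- function(x, retain_fraction = 0.95) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 rows")
  if (retain_fraction <= 0 || retain_fraction > 1)
    stop("retain_fraction must lie in (0, 1]")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  tot <- sum(v)
  if (tot <= 1e-300) stop("degenerate feature matrix: zero variance")
  share <- cumsum(v) / tot
  k <- which(share >= retain_fraction - 1e-12)[1]
  structure(list(center = pc$center,
                 rotation = pc$rotation[, seq_len(k), drop = FALSE],
                 variances = v, k = k,
                 retained_fraction = share[k], p = ncol(x)),
            class = "pca_projector")
}

#' @export
print.pca_projector <- function(x, ...) {
  cat(sprintf(
    "PCA projector: %d -> %d dimensions (%.1f%% variance retained, %.2f%% reduction)\n",
    x$p, x$k, 100 * x$retained_fraction, 100 * (1 - x$k / x$p)))
  invisible(x)
}

#' Project features onto the retained principal components
#' @param object a [fit_pca()] result.
#' @param newdata matrix (or vector for one example) with `p` columns.
#' @param ... unused.
#' @return `n x k` score matrix.
#' @export
predict.pca_projector <- function(object, newdata, ...) {
  X <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else as.matrix(newdata)
  if (ncol(X) != object$p)
    stop(sprintf("dimension mismatch: projector expects %d columns, got %d",
                 object$p, ncol(X)))
  sweep(X, 2, object$center) %*% object$rotation
}
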