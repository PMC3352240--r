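#' Conventional batch PCA of aligned spikes
#'
#' The reference route the eigenfilter replaces: mean-centre the stored
#' spikes, form the covariance matrix (normalized by n), and
#' eigendecompose it with a dense symmetric solver. Used throughout as
#' the ground-truth oracle for component comparisons.
#'
#' @param x n x d spike matrix or \code{"spike_matrix"}.
#' @param l number of leading components to return (default 2).
#' @return object of class \code{"spike_pca"}: \code{components} (l x d,
#'   orthonormal rows), \code{eigenvalues} (descending), \code{mu}.
#' @examples
#' set.seed(1)
#' X <- cbind(rnorm(500, sd = 2), rnorm(500, sd = 1))
#' spike_pca(X, l = 2)$eigenvalues
#' @export
spike_pca <- function(x, l = 2L) {
  if (inherits(x, "spike_matrix")) x <- x$spikes
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 spikes")
  d <- ncol(x)
  if (l > d) stop("require l <= d")
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  C <- crossprod(xc) / nrow(x)
  eg <- eigen(C, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  r <- sum(ev > max(ev[1], .Machine$double.eps) * 1e-12)
  if (l > r)
    warning("rank-deficient input: components beyond rank ", r,
            " have zero eigenvalue")
  structure(list(components = t(eg$vectors[, seq_len(l), drop = FALSE]),
                 eigenvalues = ev[seq_len(l)], mu = mu, d = d, l = l,
                 n = nrow(x)),
            class = "spike_pca")
}

#' @export
print.spike_pca <- function(x, ...) {
  cat(sprintf("Batch PCA oracle: %d component(s) of d = %d (n = %d spikes)\n",
              x$l, x$d, x$n))
  cat("  eigenvalues:", sprintf("%.4g", x$eigenvalues), "\n")
  invisible(x)
}

#' @export
coef.spike_pca <- function(object, ...) object$components

#' @export
predict.spike_pca <- function(object, newdata, ...) {
  project_spikes(newdata, object$components, object$mu, 1)
}

#' Resolve eigenvector sign ambiguity before row-wise comparison
#'
#' Eigenvectors (and GHA fixed points) are defined up to sign. Each row
#' of \code{W} is flipped, if necessary, so its dot product with the
#' matching row of the reference basis is nonnegative.
#'
#' @param W l x d matrix of learned components.
#' @param basis a \code{"spike_pca"} or an l x d reference matrix.
#' @return \code{W} with rows sign-flipped as needed.
#' @export
sign_align <- function(W, basis) {
  B <- if (inherits(basis, "spike_pca")) basis$components else as.matrix(basis)
  if (!all(dim(W) == dim(B))) stop("shape mismatch between W and basis")
  s <- sign(rowSums(W * B))
  s[s == 0] <- 1
  W * s
}
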