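#' Radial basis function network forward pass
#'
#' Hidden activations are Gaussian:
#' `omega_i(x) = exp(-||x - C_i||^2 / (2 d_i^2))`, and outputs are their
#' weighted sums `out_j = sum_i beta_ij omega_i(x)`.
#'
#' @param net An `rbf_net` from [rbf_fit()] (or a list with `centers`
#'   (n x p matrix), `widths` (positive, length n) and `beta` (n x q)).
#' @param inputs Feature matrix (rows = samples) or single vector.
#' @return Output matrix, one row per input sample, `q` columns.
#' @export
rbf_forward <- function(net, inputs) {
  x <- if (is.matrix(inputs)) inputs else matrix(inputs, nrow = 1L)
  centers <- as.matrix(net$centers)
  if (ncol(x) != ncol(centers))
    stop("input has ", ncol(x), " features but centers have ",
         ncol(centers), call. = FALSE)
  if (any(net$widths <= 0))
    stop("RBF widths must be strictly positive", call. = FALSE)
  d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") -
    2 * x %*% t(centers)
  d2[d2 < 0] <- 0
  omega <- exp(sweep(-d2, 2L, 2 * net$widths^2, "/"))
  omega %*% net$beta
}

#' Fit a radial basis function network
#'
#' Centers are placed by k-means on the training inputs; all widths use the
#' heuristic `d_max / sqrt(2 n_centers)` (maximum inter-center distance),
#' floored at `1e-6`; output weights are the least-squares solution of the
#' Gaussian design matrix onto one-hot class targets (pseudo-inverse, so
#' duplicate or conflicting rows cannot break the fit).
#'
#' @param inputs Feature matrix.
#' @param labels Factor of class labels.
#' @param n_centers Number of Gaussian units (must not exceed the number of
#'   training samples).
#' @param seed Seed for the k-means initialization.
#' @return An object of class `rbf_net` with `centers`, `widths`, `beta`
#'   and `class_levels`.
#' @export
rbf_fit <- function(inputs, labels, n_centers, seed = 1L) {
  x <- as.matrix(inputs)
  if (!is.factor(labels)) labels <- factor(labels)
  if (n_centers > nrow(x))
    stop("n_centers (", n_centers, ") exceeds the number of training samples (",
         nrow(x), ")", call. = FALSE)
  stopifnot(n_centers >= 1L)
  set.seed(seed)
  centers <- if (n_centers == nrow(x)) {
    x
  } else if (nrow(unique(x)) < n_centers) {
    ## fewer distinct points than centers: fall back to sampled rows
    x[sample.int(nrow(x), n_centers), , drop = FALSE]
  } else {
    kmeans(x, n_centers, iter.max = 50L, nstart = 1L)$centers
  }
  d_max <- if (n_centers > 1L) max(dist(centers)) else 0
  width <- max(d_max / sqrt(2 * n_centers), 1e-6)
  net <- list(centers = centers, widths = rep(width, n_centers),
              beta = matrix(0, n_centers, nlevels(labels)))
  omega <- exp(-(outer(rowSums(x^2), rowSums(centers^2), "+") -
                   2 * x %*% t(centers)) / (2 * width^2))
  y <- one_hot(labels)
  sv <- svd(omega)
  keep <- sv$d > max(dim(omega)) * .Machine$double.eps * sv$d[1L]
  beta <- sv$v[, keep, drop = FALSE] %*%
    ((t(sv$u[, keep, drop = FALSE]) %*% y) / sv$d[keep])
  net$beta <- beta
  net$class_levels <- levels(labels)
  structure(net, class = "rbf_net")
}
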