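#' Row-wise softmax
#'
#' Numerically stable softmax applied to each row of a matrix.
#'
#' @param z Numeric matrix of linear scores.
#' @return Matrix of the same shape whose rows are non-negative and sum to 1.
#' @keywords internal
softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' One-hot encode a factor
#' @param y Factor of class labels.
#' @return 0/1 matrix, one column per level of `y` in level order.
#' @keywords internal
one_hot <- function(y) {
  stopifnot(is.factor(y))
  m <- matrix(0, length(y), nlevels(y), dimnames = list(NULL, levels(y)))
  m[cbind(seq_along(y), as.integer(y))] <- 1
  m
}

#' Derive a stage seed from a master seed and a stage name
#'
#' Stable string hash (polynomial rolling hash mod 2^31 - 1) so that every
#' pipeline stage draws from its own reproducible stream.
#'
#' @param master_seed Integer master seed.
#' @param stage Character stage name.
#' @return A single integer in \[0, 2^31 - 2\].
#' @export
stage_seed <- function(master_seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- as.double(master_seed %% 2147483647L)
  for (code in utf8ToInt(stage)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

## column standardizer used by several classifiers; guards zero variance
fit_scaler <- function(x) {
  mu <- colMeans(x)
  s <- apply(x, 2L, sd)
  s[!is.finite(s) | s < 1e-12] <- 1
  list(center = mu, scale = s)
}

apply_scaler <- function(scaler, x) {
  sweep(sweep(x, 2L, scaler$center, "-"), 2L, scaler$scale, "/")
}
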