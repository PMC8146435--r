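#' Feed-forward network specification
#'
#' Fixed architecture used throughout the workflow: two rectifier
#' ("poslin", i.e. `max(0, x)`) hidden layers of 18 and 16 units and a
#' softmax output layer, one unit per class. Weights are held as a single
#' flat vector so metaheuristics can optimize them directly.
#'
#' @param input_dim Number of input features.
#' @param n_classes Number of output classes.
#' @param hidden Hidden layer sizes (default `c(18, 16)`).
#' @param seed Seed for He-scaled random weight initialization.
#' @return An object of class `ann_spec` with elements `dims` and `weights`.
#' @export
ann_spec <- function(input_dim, n_classes, hidden = c(18L, 16L), seed = 1L) {
  stopifnot(input_dim >= 1L, n_classes >= 2L, length(hidden) == 2L)
  dims <- as.integer(c(input_dim, hidden, n_classes))
  set.seed(seed)
  w <- numeric(0)
  for (l in 1:3) {
    fan_in <- dims[l]
    w <- c(w, rnorm(dims[l] * dims[l + 1L], 0, sqrt(2 / fan_in)),
           rep(0, dims[l + 1L]))
  }
  structure(list(dims = dims, weights = w), class = "ann_spec")
}

#' Number of weights of an architecture
#' @param dims Integer vector `c(input, hidden1, hidden2, classes)`.
#' @return Total number of weights and biases.
#' @export
ann_n_weights <- function(dims) {
  sum((dims[-length(dims)] + 1L) * dims[-1L])
}

#' Forward pass of the feed-forward network
#'
#' `scores = softmax(W3 relu(W2 relu(W1 x + b1) + b2) + b3)`; every row of
#' the result is a probability vector over classes.
#'
#' @param spec An [ann_spec()].
#' @param inputs Numeric matrix (rows = samples) or vector of length
#'   `input_dim`.
#' @return Matrix of per-class scores, rows summing to 1.
#' @export
ann_forward <- function(spec, inputs) {
  stopifnot(inherits(spec, "ann_spec"))
  x <- if (is.matrix(inputs)) inputs else matrix(inputs, nrow = 1L)
  if (ncol(x) != spec$dims[1L])
    stop("input has ", ncol(x), " features but the network expects ",
         spec$dims[1L], call. = FALSE)
  cpp_ann_forward(spec$weights, spec$dims, x)
}

#' Gradient training of the feed-forward network
#'
#' Full-batch gradient descent on cross-entropy plus an L2 weight penalty,
#' with heavy-ball momentum and step rejection (a step that would increase
#' the loss is discarded and the learning rate halved), so the recorded
#' per-epoch loss is non-increasing. Deterministic given the initial spec.
#'
#' @param spec An [ann_spec()] providing the initial weights.
#' @param inputs Numeric feature matrix.
#' @param labels Factor of class labels; its number of levels must match
#'   the output layer.
#' @param l2_penalty L2 penalty on weights (default `1e-4`).
#' @param max_epochs Number of epochs; `0` returns `spec` unchanged.
#' @param learning_rate Initial step size.
#' @param momentum Heavy-ball coefficient.
#' @return The trained `ann_spec`, with the per-epoch loss attached as
#'   attribute `"loss_history"`.
#' @export
ann_train_gradient <- function(spec, inputs, labels, l2_penalty = 1e-4,
                               max_epochs = 150L, learning_rate = 0.3,
                               momentum = 0.9) {
  stopifnot(inherits(spec, "ann_spec"))
  x <- as.matrix(inputs)
  if (nrow(x) == 0L) stop("empty training set", call. = FALSE)
  if (!is.factor(labels)) labels <- factor(labels)
  if (nlevels(labels) != spec$dims[4L])
    stop("labels have ", nlevels(labels), " levels but the network has ",
         spec$dims[4L], " outputs", call. = FALSE)
  if (ncol(x) != spec$dims[1L])
    stop("input has ", ncol(x), " features but the network expects ",
         spec$dims[1L], call. = FALSE)
  if (max_epochs == 0L) {
    attr(spec, "loss_history") <- numeric(0)
    return(spec)
  }
  y <- one_hot(labels)
  fit <- cpp_ann_train(spec$weights, spec$dims, x, y, l2_penalty,
                       as.integer(max_epochs), learning_rate, momentum)
  out <- structure(list(dims = spec$dims, weights = as.numeric(fit$weights)),
                   class = "ann_spec")
  attr(out, "loss_history") <- as.numeric(fit$loss)
  out
}

#' Mean squared error of the network's softmax outputs
#'
#' Cost used by the metaheuristic stages: mean over all entries of the
#' squared difference between softmax outputs and one-hot targets.
#'
#' @param spec An [ann_spec()].
#' @param inputs Feature matrix.
#' @param labels Factor of class labels.
#' @return Scalar MSE.
#' @export
ann_mse <- function(spec, inputs, labels) {
  stopifnot(inherits(spec, "ann_spec"))
  if (!is.factor(labels)) labels <- factor(labels)
  cpp_ann_mse(spec$weights, spec$dims, as.matrix(inputs), one_hot(labels))
}
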