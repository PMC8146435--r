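## Five classifiers behind one contract: every trainer returns an object of
## class c("<kind>", "nitro_classifier"); predict(object, newdata,
## type = "class") gives a factor of labels, type = "score" a matrix of
## normalized per-class scores (rows sum to 1) in a fixed class order.

new_classifier <- function(kind, fields, class_levels) {
  structure(c(fields, list(kind = kind, class_levels = class_levels)),
            class = c(paste0("nitro_", kind), "nitro_classifier"))
}

#' Predict classes or per-class scores
#'
#' @param object A fitted classifier.
#' @param newdata Feature matrix.
#' @param type `"class"` for labels (argmax of scores, earlier class wins
#'   ties), `"score"` for the normalized score matrix.
#' @param ... Unused.
#' @return Factor of labels or a score matrix with one column per class.
#' @export
predict.nitro_classifier <- function(object, newdata,
                                     type = c("class", "score"), ...) {
  type <- match.arg(type)
  s <- classifier_scores(object, as.matrix(newdata))
  colnames(s) <- object$class_levels
  if (type == "score") return(s)
  factor(object$class_levels[max.col(s, ties.method = "first")],
         levels = object$class_levels)
}

classifier_scores <- function(object, x) UseMethod("classifier_scores")

#' Train the feed-forward network with a metaheuristic
#'
#' The metaheuristic (imperialist competitive algorithm or harmony search)
#' searches over initial weight vectors of the fixed 18 & 16 architecture;
#' the cost of a candidate is the training mean squared error of the
#' softmax outputs after a short deterministic backpropagation run from
#' that initialization, and the returned model is the backprop-trained
#' network of the best candidate. Inputs are standardized internally with
#' training statistics.
#'
#' @param inputs Feature matrix.
#' @param labels Factor with at least two classes present.
#' @param algorithm `"ica"` or `"hs"`.
#' @param params An [ica_params()] or [hs_params()]; defaults are used when
#'   `NULL`.
#' @param inner_epochs Backpropagation epochs run inside the cost function
#'   and for the final model.
#' @param l2_penalty L2 penalty of the inner training.
#' @param weight_bound Box half-width for candidate initial weights.
#' @param hidden Hidden layer sizes.
#' @param seed Seed controlling the metaheuristic (overrides `params$seed`
#'   when given).
#' @return A `nitro_classifier`; the optimizer's cost history is stored in
#'   field `history`.
#' @export
train_ann_metaheuristic <- function(inputs, labels,
                                    algorithm = c("ica", "hs"),
                                    params = NULL, inner_epochs = 40L,
                                    l2_penalty = 1e-4, weight_bound = 0.5,
                                    hidden = c(18L, 16L), seed = NULL) {
  algorithm <- match.arg(algorithm)
  x <- as.matrix(inputs)
  if (!is.factor(labels)) labels <- factor(labels)
  labels <- droplevels(labels)
  if (nlevels(labels) < 2L)
    stop("need at least two classes present in the training data",
         call. = FALSE)
  scaler <- fit_scaler(x)
  xs <- apply_scaler(scaler, x)
  dims <- as.integer(c(ncol(xs), hidden, nlevels(labels)))
  nw <- ann_n_weights(dims)
  y <- one_hot(labels)

  cost <- function(w) {
    fit <- cpp_ann_train(w, dims, xs, y, l2_penalty,
                         as.integer(inner_epochs), 0.3, 0.9)
    cpp_ann_mse(fit$weights, dims, xs, y)
  }
  if (is.null(params)) {
    params <- if (algorithm == "ica") ica_params(population = 20L,
                                                 generations = 10L)
              else hs_params(memory_size = 15L, improvisations = 200L)
  }
  if (!is.null(seed)) params$seed <- as.integer(seed)
  obj <- objective_continuous(cost, -weight_bound, weight_bound, nw)
  res <- if (algorithm == "ica") ica_optimize(obj, params)
         else hs_optimize(obj, params)
  fit <- cpp_ann_train(res$best$siv, dims, xs, y, l2_penalty,
                       as.integer(inner_epochs), 0.3, 0.9)
  spec <- structure(list(dims = dims, weights = as.numeric(fit$weights)),
                    class = "ann_spec")
  new_classifier(paste0("ann_", algorithm),
                 list(spec = spec, scaler = scaler, history = res$history,
                      cost = res$best$cost),
                 levels(labels))
}

#' @export
classifier_scores.nitro_ann_ica <- function(object, x)
  ann_forward(object$spec, apply_scaler(object$scaler, x))

#' @export
classifier_scores.nitro_ann_hs <- classifier_scores.nitro_ann_ica

#' K-nearest-neighbour classification
#'
#' Brute-force Euclidean KNN. Each test row is labelled by the modal class
#' of its `k` nearest training rows; ties are broken by the smallest summed
#' neighbour distance and then by class order. Scores are the neighbour
#' class fractions.
#'
#' @param train_inputs,train_labels Training features and labels.
#' @param test_inputs Feature matrix to classify.
#' @param k Number of neighbours, `1 <= k <=` number of training rows.
#' @return List with `labels` (factor) and `scores` (matrix of neighbour
#'   fractions).
#' @export
knn_fit_predict <- function(train_inputs, train_labels, test_inputs, k) {
  trx <- as.matrix(train_inputs)
  tex <- as.matrix(test_inputs)
  if (!is.factor(train_labels)) train_labels <- factor(train_labels)
  if (k < 1L || k > nrow(trx))
    stop("k must be between 1 and the number of training samples",
         call. = FALSE)
  nlev <- nlevels(train_labels)
  scores <- matrix(0, nrow(tex), nlev,
                   dimnames = list(NULL, levels(train_labels)))
  lab_idx <- integer(nrow(tex))
  tr_t <- t(trx)
  for (i in seq_len(nrow(tex))) {
    d <- sqrt(colSums((tr_t - tex[i, ])^2))
    nb <- order(d)[seq_len(k)]
    counts <- tabulate(train_labels[nb], nbins = nlev)
    scores[i, ] <- counts / k
    top <- which(counts == max(counts))
    if (length(top) > 1L) {
      sumd <- vapply(top, function(cl)
        sum(d[nb][train_labels[nb] == levels(train_labels)[cl]]),
        numeric(1L))
      top <- top[order(sumd, top)][1L]
    }
    lab_idx[i] <- top[1L]
  }
  list(labels = factor(levels(train_labels)[lab_idx],
                       levels = levels(train_labels)),
       scores = scores)
}

#' KNN classifier object
#'
#' Stores the training set; `k` may be fixed or selected on a validation
#' set by accuracy over `k_grid` (smallest k wins ties).
#'
#' @param inputs,labels Training data.
#' @param k Number of neighbours; `NULL` to select on validation data.
#' @param validation_inputs,validation_labels Held-out data used to pick
#'   `k` when `k = NULL` (defaults to the training data).
#' @param k_grid Candidate neighbourhood sizes.
#' @return A `nitro_classifier` with field `k`.
#' @export
knn_classifier <- function(inputs, labels, k = NULL,
                           validation_inputs = NULL,
                           validation_labels = NULL,
                           k_grid = c(1L, 3L, 5L, 7L, 9L)) {
  x <- as.matrix(inputs)
  if (!is.factor(labels)) labels <- factor(labels)
  labels <- droplevels(labels)
  if (is.null(k)) {
    if (is.null(validation_inputs)) {
      validation_inputs <- x
      validation_labels <- labels
    }
    k_grid <- k_grid[k_grid <= nrow(x)]
    acc <- vapply(k_grid, function(kk)
      mean(knn_fit_predict(x, labels, validation_inputs, kk)$labels ==
             validation_labels), numeric(1L))
    k <- k_grid[which.max(acc)]
  }
  new_classifier("knn", list(train_x = x, train_y = labels, k = k),
                 levels(labels))
}

#' @export
classifier_scores.nitro_knn <- function(object, x)
  knn_fit_predict(object$train_x, object$train_y, x, object$k)$scores

## Wilks' lambda of variable set S: det(W)/det(T)
wilks_lambda <- function(x, y, vars) {
  if (length(vars) == 0L) return(1)
  xs <- x[, vars, drop = FALSE]
  tot <- crossprod(sweep(xs, 2L, colMeans(xs)))
  within <- matrix(0, length(vars), length(vars))
  for (lv in levels(y)) {
    xi <- xs[y == lv, , drop = FALSE]
    if (nrow(xi) > 0L)
      within <- within + crossprod(sweep(xi, 2L, colMeans(xi)))
  }
  dW <- det(within); dT <- det(tot)
  if (dT <= 0) return(1)
  max(dW / dT, .Machine$double.eps)
}

## partial F for adding `v` to set S (classic stepwise discriminant formula)
partial_f_enter <- function(x, y, S, v) {
  n <- nrow(x); g <- nlevels(y); p <- length(S)
  l0 <- wilks_lambda(x, y, S)
  l1 <- wilks_lambda(x, y, c(S, v))
  ((n - g - p) / (g - 1)) * (l0 / l1 - 1)
}

#' Linear discriminant analysis with optional stepwise selection
#'
#' Stepwise variable selection by Wilks'-lambda partial F: at each round
#' the variable with the largest entry F joins if `F >= f_enter`, then any
#' included variable whose removal F falls below `f_remove` leaves. If no
#' variable passes entry the model falls back to all variables with a
#' warning. Discrimination uses class means with a shared pooled
#' covariance (ridge `1e-8` on the diagonal) and class-proportion priors;
#' scores are the class posteriors.
#'
#' @param inputs Feature matrix.
#' @param labels Factor; every present class needs at least two samples.
#' @param stepwise Run stepwise selection (default `TRUE`).
#' @param f_enter,f_remove Entry and removal thresholds (conventional
#'   3.84 / 2.71).
#' @param ridge Diagonal regularization of the pooled covariance.
#' @return A `nitro_classifier` with field `selected` (column indices used).
#' @export
lda_fit <- function(inputs, labels, stepwise = TRUE,
                    f_enter = 3.84, f_remove = 2.71, ridge = 1e-8) {
  x <- as.matrix(inputs)
  if (!is.factor(labels)) labels <- factor(labels)
  labels <- droplevels(labels)
  if (nlevels(labels) < 2L)
    stop("need at least two classes", call. = FALSE)
  if (any(tabulate(labels) < 2L))
    stop("every class needs at least two samples", call. = FALSE)
  p <- ncol(x)
  selected <- seq_len(p)
  if (stepwise && p > 1L) {
    S <- integer(0)
    remaining <- seq_len(p)
    repeat {
      changed <- FALSE
      if (length(remaining)) {
        fs <- vapply(remaining, function(v) partial_f_enter(x, labels, S, v),
                     numeric(1L))
        if (max(fs) >= f_enter) {
          v <- remaining[which.max(fs)]
          S <- c(S, v)
          remaining <- setdiff(remaining, v)
          changed <- TRUE
        }
      }
      if (length(S) > 1L) {
        frem <- vapply(S, function(v)
          partial_f_enter(x, labels, setdiff(S, v), v), numeric(1L))
        drop_v <- S[frem < f_remove]
        if (length(drop_v)) {
          S <- setdiff(S, drop_v[1L])
          remaining <- c(remaining, drop_v[1L])
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    if (length(S) == 0L) {
      warning("no variable passed the entry threshold; using all variables")
      S <- seq_len(p)
    }
    selected <- sort(S)
  }
  xs <- x[, selected, drop = FALSE]
  means <- do.call(rbind, lapply(levels(labels), function(lv)
    colMeans(xs[labels == lv, , drop = FALSE])))
  rownames(means) <- levels(labels)
  pooled <- matrix(0, ncol(xs), ncol(xs))
  for (lv in levels(labels)) {
    xi <- xs[labels == lv, , drop = FALSE]
    pooled <- pooled + crossprod(sweep(xi, 2L, colMeans(xi)))
  }
  pooled <- pooled / (nrow(xs) - nlevels(labels))
  pooled <- pooled + diag(ridge, ncol(xs))
  prec <- solve(pooled)
  priors <- tabulate(labels) / length(labels)
  new_classifier("lda",
                 list(selected = selected, means = means, precision = prec,
                      priors = priors),
                 levels(labels))
}

#' @export
classifier_scores.nitro_lda <- function(object, x) {
  xs <- x[, object$selected, drop = FALSE]
  ## log posterior up to a constant: x' P mu_k - 0.5 mu_k' P mu_k + log pi_k
  a <- xs %*% object$precision %*% t(object$means)
  const <- -0.5 * rowSums((object$means %*% object$precision) *
                            object$means) + log(object$priors)
  softmax_rows(sweep(a, 2L, const, "+"))
}

#' Radial basis function network classifier
#'
#' Delegates to [rbf_fit()] / [rbf_forward()]; per-class scores are the
#' softmax of the network outputs and labels their argmax. The default
#' hidden layer holds one Gaussian unit per class.
#'
#' @param inputs,labels Training data.
#' @param n_centers Number of Gaussian units (default: number of classes).
#' @param seed Seed for the k-means center placement.
#' @return A `nitro_classifier` with the fitted `rbf_net` in field `net`.
#' @export
rbf_classifier <- function(inputs, labels, n_centers = NULL, seed = 1L) {
  if (!is.factor(labels)) labels <- factor(labels)
  labels <- droplevels(labels)
  if (is.null(n_centers)) n_centers <- nlevels(labels)
  net <- rbf_fit(as.matrix(inputs), labels, n_centers, seed)
  new_classifier("rbf", list(net = net), levels(labels))
}

#' @export
classifier_scores.nitro_rbf <- function(object, x)
  softmax_rows(rbf_forward(object$net, x))
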