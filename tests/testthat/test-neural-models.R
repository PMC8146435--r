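test_that("softmax output layer behaves like softmax", {
  spec <- ann_spec(3, 4, seed = 1L)
  spec$weights[] <- 0
  p <- ann_forward(spec, matrix(rnorm(15), 5, 3))
  expect_equal(p, matrix(0.25, 5, 4))

  # shifting every output-layer bias by a constant leaves scores unchanged
  spec2 <- ann_spec(2, 3, hidden = c(4L, 3L), seed = 2L)
  p1 <- ann_forward(spec2, matrix(1:6 / 10, 3, 2))
  nb <- length(spec2$weights)
  spec2$weights[(nb - 2):nb] <- spec2$weights[(nb - 2):nb] + 7
  p2 <- ann_forward(spec2, matrix(1:6 / 10, 3, 2))
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("forward pass matches hand arithmetic on a minimal network", {
  # 2 inputs -> 1 -> 1 -> 2 classes, weights set by hand
  spec <- ann_spec(2, 2, hidden = c(1L, 1L), seed = 1L)
  # layer 1: w = (0.5, -1), b = 0.1; layer 2: w = 2, b = -0.05
  # output: w = (1.5, -0.3), b = (0, 0.2)
  spec$weights <- c(0.5, -1, 0.1, 2, -0.05, 1.5, -0.3, 0, 0.2)
  x <- c(0.4, 0.3)
  h1 <- max(0, 0.5 * 0.4 - 1 * 0.3 + 0.1)
  h2 <- max(0, 2 * h1 - 0.05)
  z <- c(1.5 * h2 + 0, -0.3 * h2 + 0.2)
  expected <- exp(z) / sum(exp(z))
  expect_equal(ann_forward(spec, x)[1, ], expected, tolerance = 1e-12)
})

test_that("forward scores always form probability rows", {
  set.seed(6)
  spec <- ann_spec(5, 4, seed = 3L)
  p <- ann_forward(spec, matrix(rnorm(200, sd = 3), 40, 5))
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), rep(1, 40), tolerance = 1e-9)
  expect_error(ann_forward(spec, matrix(1, 2, 3)), "features")
})

test_that("gradient training fits a separable toy problem monotonically", {
  x <- rbind(c(0, 0), c(0, 1), c(3, 3), c(3, 4))
  y <- factor(c("a", "a", "b", "b"))
  # the two groups are linearly separable: verified by an exhaustive check
  # over axis-aligned boundaries
  cuts <- sapply(seq(-1, 5, by = 0.5), function(t) all((x[, 1] > t) == (y == "b")))
  expect_true(any(cuts))
  spec <- ann_spec(2, 2, seed = 5L)
  fit <- ann_train_gradient(spec, x, y, max_epochs = 500L)
  expect_true(all(diff(attr(fit, "loss_history")) <= 1e-12))
  pred <- max.col(ann_forward(fit, x))
  expect_equal(pred, as.integer(y))
})

test_that("an overwhelming L2 penalty collapses the network", {
  x <- matrix(rnorm(40), 20, 2)
  y <- factor(rep(c("a", "b"), 10))
  spec <- ann_spec(2, 2, seed = 2L)
  fit <- ann_train_gradient(spec, x, y, l2_penalty = 1e4, max_epochs = 300L)
  expect_lt(sqrt(sum(fit$weights^2)), 0.05 * sqrt(sum(spec$weights^2)))
  p <- ann_forward(fit, x)
  expect_equal(p, matrix(0.5, 20, 2), tolerance = 0.05)
})

test_that("zero training epochs return the spec unchanged", {
  spec <- ann_spec(2, 2, seed = 9L)
  fit <- ann_train_gradient(spec, matrix(rnorm(8), 4, 2),
                            factor(c("a", "b", "a", "b")), max_epochs = 0L)
  expect_identical(fit$weights, spec$weights)
})

test_that("RBF forward follows the Gaussian kernel analytically", {
  net <- list(centers = rbind(c(0, 0), c(2, 0)), widths = c(1, 1),
              beta = diag(2))
  # x on a center: that unit's activation is exactly 1
  out <- rbf_forward(net, c(0, 0))
  expect_equal(out[1, 1], 1)
  # distance = width * sqrt(2) gives exp(-1)
  out2 <- rbf_forward(net, c(sqrt(2), 0))
  expect_equal(out2[1, 1], exp(-1))
  # zero output weights give zero outputs
  net$beta <- matrix(0, 2, 2)
  expect_equal(rbf_forward(net, rbind(c(1, 1), c(0, 3))),
               matrix(0, 2, 2))
  net$widths <- c(1, -1)
  expect_error(rbf_forward(net, c(0, 0)), "positive")
})

test_that("RBF forward equals a naive two-loop evaluation", {
  set.seed(13)
  net <- list(centers = matrix(rnorm(12), 4, 3),
              widths = runif(4, 0.5, 2), beta = matrix(rnorm(8), 4, 2))
  x <- matrix(rnorm(15), 5, 3)
  naive <- matrix(0, 5, 2)
  for (i in 1:5) {
    for (j in 1:2) {
      for (u in 1:4) {
        om <- exp(-sum((x[i, ] - net$centers[u, ])^2) /
                    (2 * net$widths[u]^2))
        naive[i, j] <- naive[i, j] + net$beta[u, j] * om
      }
    }
  }
  expect_equal(rbf_forward(net, x), naive, tolerance = 1e-10)
})

test_that("full-rank RBF fits interpolate their training data", {
  set.seed(21)
  x <- matrix(runif(20, -2, 2), 10, 2)
  y <- factor(sample(c("a", "b", "c"), 10, replace = TRUE))
  net <- rbf_fit(x, y, n_centers = 10L, seed = 1L)
  out <- rbf_forward(net, x)
  expect_equal(levels(y)[max.col(out)], as.character(y))
  # oracle: solve the exact Gaussian design directly
  d2 <- as.matrix(dist(x))^2
  g <- exp(-d2 / (2 * net$widths[1]^2))
  beta <- solve(g, nitrospec:::one_hot(y))
  expect_equal(net$beta, beta, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("degenerate RBF training inputs are handled", {
  x <- matrix(runif(10), 5, 2)
  y <- factor(rep("only", 5))
  net <- rbf_fit(x, y, 2L, seed = 1L)
  expect_equal(max.col(rbf_forward(net, x)), rep(1L, 5))

  # duplicate rows with conflicting labels: pseudo-inverse keeps it solvable
  xd <- rbind(c(1, 1), c(1, 1), c(0, 0))
  yd <- factor(c("a", "b", "a"))
  expect_silent(net2 <- rbf_fit(xd, yd, 3L, seed = 1L))
  expect_true(all(is.finite(net2$beta)))
  expect_error(rbf_fit(x, y, 6L), "exceeds")
})
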