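test_that("metaheuristic-trained networks separate clean Gaussian blobs", {
  # centers 3 apart with sd 0.1: the Bayes error of these blobs is
  # Phi(-3 / (0.1 * sqrt(2)) / 2) ~ 0, so high held-out accuracy is
  # achievable and expected
  blobs <- gaussian_blobs(n = 40L, sd = 0.1, gap = 3, seed = 1L)
  test <- gaussian_blobs(n = 25L, sd = 0.1, gap = 3, seed = 99L)
  fit <- train_ann_metaheuristic(blobs$x, blobs$y, "ica", seed = 2L)
  acc <- mean(predict(fit, test$x) == test$y)
  expect_gte(acc, 0.95)
  fit_hs <- train_ann_metaheuristic(blobs$x, blobs$y, "hs", seed = 2L)
  expect_gte(mean(predict(fit_hs, test$x) == test$y), 0.95)
})

test_that("metaheuristic training is deterministic and degrades gracefully", {
  blobs <- gaussian_blobs(n = 15L, seed = 3L)
  f1 <- train_ann_metaheuristic(blobs$x, blobs$y, "ica", seed = 7L)
  f2 <- train_ann_metaheuristic(blobs$x, blobs$y, "ica", seed = 7L)
  expect_identical(predict(f1, blobs$x), predict(f2, blobs$x))

  # zero generations: best of the random initial population, but the
  # contract (normalized scores) still holds
  f0 <- train_ann_metaheuristic(blobs$x, blobs$y, "ica",
    params = ica_params(population = 8L, generations = 0L,
                        n_imperialists = 2L, seed = 1L))
  s <- predict(f0, blobs$x, type = "score")
  expect_equal(rowSums(s), rep(1, nrow(blobs$x)), tolerance = 1e-6)
  expect_error(train_ann_metaheuristic(blobs$x,
                                       factor(rep("a", nrow(blobs$x))),
                                       "ica"),
               "two classes")
})

test_that("KNN matches an exhaustive distance-sort oracle", {
  set.seed(31)
  trx <- matrix(rnorm(60), 30, 2)
  try_ <- factor(sample(c("a", "b", "c"), 30, replace = TRUE))
  tex <- matrix(rnorm(16), 8, 2)
  res <- knn_fit_predict(trx, try_, tex, k = 5L)
  for (i in 1:8) {
    d <- sqrt(colSums((t(trx) - tex[i, ])^2))
    nb <- order(d)[1:5]
    counts <- table(try_[nb])
    expect_equal(unname(res$scores[i, names(counts)]),
                 unname(as.numeric(counts) / 5))
    top <- names(counts)[counts == max(counts)]
    if (length(top) == 1L) expect_equal(as.character(res$labels[i]), top)
    expect_true(as.character(res$labels[i]) %in% top)
  }
})

test_that("KNN edge cases follow the contract", {
  res <- knn_fit_predict(matrix(c(0, 0), 1, 2), factor("a"),
                         matrix(rnorm(10), 5, 2), k = 1L)
  expect_equal(as.character(res$labels), rep("a", 5))

  set.seed(5)
  x <- matrix(rnorm(20), 10, 2)
  y <- factor(sample(c("a", "b"), 10, replace = TRUE))
  self <- knn_fit_predict(x, y, x, k = 1L)
  expect_equal(self$labels, y, ignore_attr = TRUE)
  expect_error(knn_fit_predict(x, y, x, k = 11L), "between")

  # tie on counts resolved by smaller summed distance
  trx <- matrix(c(0, 0, 1, 1, 10, 10, 10.5, 10.5), 4, 2, byrow = TRUE)
  try_ <- factor(c("a", "a", "b", "b"))
  res2 <- knn_fit_predict(trx, try_, matrix(c(5, 5), 1, 2), k = 4L)
  expect_equal(as.character(res2$labels), "a")
})

test_that("stepwise LDA keeps informative variables and drops noise", {
  set.seed(17)
  n <- 60
  x <- cbind(c(rnorm(n, -1, 0.5), rnorm(n, 1, 0.5)), rnorm(2 * n))
  y <- factor(rep(c("a", "b"), each = n))
  # direct partial-F oracle for entering each variable first
  f_direct <- vapply(1:2, function(v)
    nitrospec:::partial_f_enter(x, y, integer(0), v), numeric(1))
  expect_gt(f_direct[1], 3.84)
  expect_lt(f_direct[2], 3.84)
  fit <- lda_fit(x, y, stepwise = TRUE)
  expect_identical(fit$selected, 1L)
})

test_that("LDA posteriors and boundaries match closed forms", {
  set.seed(23)
  # no-signal limit: posteriors approach the priors
  x <- matrix(rnorm(300), 150, 2)
  y <- factor(rep(c("a", "b", "b"), 50))
  fit <- lda_fit(x, y, stepwise = FALSE)
  sc <- predict(fit, matrix(rnorm(40), 20, 2), type = "score")
  expect_equal(colMeans(sc), c(a = 1 / 3, b = 2 / 3), tolerance = 0.1)

  # 1-D two-class boundary: the analytic midpoint of the class means
  x1 <- matrix(c(rnorm(400, 0, 1), rnorm(400, 4, 1)), ncol = 1)
  y1 <- factor(rep(c("lo", "hi"), each = 400), levels = c("lo", "hi"))
  fit1 <- lda_fit(x1, y1, stepwise = FALSE)
  grid <- matrix(seq(0, 4, by = 1e-3), ncol = 1)
  s <- predict(fit1, grid, type = "score")
  boundary <- grid[which.min(abs(s[, "lo"] - 0.5)), 1]
  expect_lt(abs(boundary - mean(c(mean(x1[y1 == "lo", ]),
                                  mean(x1[y1 == "hi", ])))), 0.05)
  expect_error(lda_fit(rbind(c(0, 0), c(1, 1), c(2, 2)),
                       factor(c("a", "a", "b"))),
               "two samples")
})

test_that("non-stepwise LDA agrees with an independent implementation", {
  set.seed(41)
  x <- rbind(matrix(rnorm(120, 0), 60, 2),
             matrix(rnorm(120, 1.5), 60, 2))
  y <- factor(rep(c("a", "b"), each = 60))
  mine <- lda_fit(x, y, stepwise = FALSE)
  ref <- MASS::lda(x, grouping = y)
  newx <- matrix(rnorm(30, 0.7), 15, 2)
  expect_equal(as.character(predict(mine, newx)),
               as.character(predict(ref, newx)$class))
  expect_equal(unname(predict(mine, newx, type = "score")),
               unname(predict(ref, newx)$posterior), tolerance = 1e-6)
})

test_that("the RBF classifier solves XOR by exact interpolation", {
  x <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  y <- factor(c("a", "b", "b", "a"))
  fit <- rbf_classifier(x, y, n_centers = 4L, seed = 1L)
  expect_equal(predict(fit, x), y, ignore_attr = TRUE)

  # one center saturates: far-away inputs get identical scores
  f1 <- rbf_classifier(x, y, n_centers = 1L, seed = 1L)
  far <- predict(f1, rbind(c(50, 50), c(-60, 40)), type = "score")
  expect_equal(far[1, ], far[2, ], tolerance = 1e-9)
})

test_that("all five classifiers honour the shared score contract", {
  d <- generate_dataset(small_config(n = 25L))
  pre <- preprocess_dataset(d)
  band <- function(nm) which.min(abs(pre$wavelengths - nm))
  x <- pre$spectra[, c(band(723), band(781), band(901))]
  y <- pre$labels
  set.seed(2)
  idx <- sample(nrow(x))
  tr <- idx[1:60]
  te <- idx[61:100]
  fits <- list(
    ica = train_ann_metaheuristic(x[tr, ], y[tr], "ica",
      params = ica_params(population = 10L, generations = 3L,
                          n_imperialists = 2L, seed = 1L)),
    hs = train_ann_metaheuristic(x[tr, ], y[tr], "hs",
      params = hs_params(memory_size = 8L, improvisations = 40L, seed = 1L)),
    knn = knn_classifier(x[tr, ], y[tr], k = 5L),
    lda = lda_fit(x[tr, ], y[tr]),
    rbf = rbf_classifier(x[tr, ], y[tr], seed = 1L)
  )
  for (nm in names(fits)) {
    s <- predict(fits[[nm]], x[te, ], type = "score")
    lab <- predict(fits[[nm]], x[te, ], type = "class")
    expect_equal(rowSums(s), rep(1, 40), tolerance = 1e-6, label = nm)
    expect_identical(as.integer(lab), max.col(s, ties.method = "first"),
                     label = nm)
  }

  # order of training rows is irrelevant for the closed-form classifiers
  perm <- sample(tr)
  knn_p <- knn_classifier(x[perm, ], y[perm], k = 5L)
  expect_identical(predict(fits$knn, x[te, ]), predict(knn_p, x[te, ]))
  lda_p <- lda_fit(x[perm, ], y[perm])
  expect_equal(predict(fits$lda, x[te, ], type = "score"),
               predict(lda_p, x[te, ], type = "score"), tolerance = 1e-10)
})
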