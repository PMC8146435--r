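mk_votes <- function(labels, lev = c("A", "B", "C")) {
  lapply(labels, function(v) factor(v, levels = lev))
}

test_that("majority vote follows plurality with the documented tie rule", {
  v <- mk_votes(list("A", "A", "A", "B", "C"))
  expect_equal(as.character(majority_vote(v)), "A")

  v2 <- mk_votes(list("B", "B", "B", "B", "B"))
  scores <- lapply(1:5, function(i)
    matrix(c(0.9, 0.05, 0.05), 1, dimnames = list(NULL, c("A", "B", "C"))))
  expect_equal(as.character(majority_vote(v2, scores)), "B")

  # 2-2-1 tie: summed scores decide (A = 1.4, B = 1.7)
  v3 <- mk_votes(list("A", "A", "B", "B", "C"))
  sc <- list(c(0.5, 0.2), c(0.5, 0.2), c(0.1, 0.5), c(0.2, 0.5),
             c(0.1, 0.3))
  scores3 <- lapply(sc, function(s)
    matrix(c(s[1], s[2], 1 - sum(s)), 1,
           dimnames = list(NULL, c("A", "B", "C"))))
  expect_equal(as.character(majority_vote(v3, scores3)), "B")
  # and with no scores the earlier class wins the tie
  expect_equal(as.character(majority_vote(v3)), "A")

  expect_error(majority_vote(list()), "at least one")
})

test_that("confusion matrices tally actual vs predicted counts", {
  lev <- c("x", "y", "z")
  a <- factor(c("x", "x", "y", "z", "z", "z"), levels = lev)
  p <- factor(c("x", "y", "y", "z", "x", "z"), levels = lev)
  m <- confusion(a, p)
  expect_equal(m["x", ], c(x = 1L, y = 1L, z = 0L))
  expect_equal(m["z", ], c(x = 1L, y = 0L, z = 2L))
  expect_equal(sum(m), 6L)

  perfect <- confusion(a, a)
  expect_equal(diag(perfect), c(x = 2L, y = 1L, z = 3L))
  expect_equal(sum(perfect) - sum(diag(perfect)), 0L)

  empty <- confusion(factor(character(), levels = lev),
                     factor(character(), levels = lev))
  expect_equal(sum(empty), 0L)
  expect_error(confusion(c("x", "q"), c("x", "x"), lev), "unknown label")
  expect_error(confusion(c("x"), c("x", "y"), lev), "equal length")
})

test_that("CCR and misclassification follow their table conventions", {
  m <- diag(c(5L, 3L, 2L))
  expect_equal(ccr(m), 100)
  expect_error(ccr(matrix(0L, 2, 2)), "zero total")
  rownames(m) <- colnames(m) <- c("a", "b", "c")
  expect_equal(misclassified_pct(m, "a"), 0)
  m["a", "b"] <- 10L
  expect_equal(misclassified_pct(m, "a"), 200)
  m["b", "b"] <- 0L
  expect_error(misclassified_pct(m, "b"), "zero diagonal")
})

test_that("per-class metrics agree with a hand tally in both conventions", {
  m <- matrix(c(8L, 2L, 1L, 9L), 2, 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("a", "b")))
  std <- per_class_metrics(m, "standard")
  expect_equal(std$recall, c(100 * 8 / 10, 100 * 9 / 10))
  expect_equal(std$precision, c(100 * 8 / 9, 100 * 9 / 11))
  expect_equal(std$accuracy, c(85, 85))
  expect_equal(std$specificity, c(100 * 9 / 10, 100 * 8 / 10))
  expect_equal(std$f,
               2 * std$recall * std$precision / (std$recall + std$precision))
  pub <- per_class_metrics(m, "published")
  expect_equal(pub$recall, c(100 * 8 / 9, 100 * 9 / 11))
  expect_equal(pub$precision, c(100 * 8 / 10, 100 * 9 / 10))
})

test_that("AUC equals the Mann-Whitney statistic and its conventions", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 6), c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))$auc, 0.5)

  set.seed(19)
  s <- round(runif(8), 1)  # rounded to force some ties
  pos <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE)
  # U-statistic oracle by full enumeration of positive/negative pairs
  u <- 0
  for (i in which(pos)) {
    for (j in which(!pos)) {
      u <- u + (s[i] > s[j]) + 0.5 * (s[i] == s[j])
    }
  }
  r <- roc_auc(s, pos)
  expect_equal(r$auc, u / (sum(pos) * sum(!pos)))
  # independent implementation cross-check
  expect_equal(r$auc,
               as.numeric(pROC::auc(pROC::roc(pos, s, quiet = TRUE,
                                              direction = "<"))))
  # invariance under strictly monotone transforms
  expect_equal(roc_auc(exp(3 * s), pos)$auc, r$auc)
  expect_error(roc_auc(s, rep(TRUE, 8)), "both classes")
})

test_that("the paired t test matches closed-form arithmetic", {
  r0 <- paired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$t, 0)
  expect_equal(r0$p_value, 1)

  a <- c(2.0, 3.5, 1.0)
  b <- c(1.5, 2.0, 2.0)
  d <- a - b
  r <- paired_t_test(a, b)
  expect_equal(r$mean_difference, mean(d))
  expect_equal(r$df, 2L)
  expect_equal(r$t, mean(d) / (sd(d) / sqrt(3)))
  expect_equal(r$p_value, 2 * pt(-abs(r$t), 2))
  expect_error(paired_t_test(1, 2), "two pairs")
})

test_that("the Kjeldahl formula converts titration volumes to percent N", {
  expect_equal(kjeldahl_nitrogen(10, 10, 0.1, 0.5), 0)
  expect_equal(kjeldahl_nitrogen(10, 0.2, 0.1, 0.5), 2.744)
  expect_warning(out <- kjeldahl_nitrogen(1, 2, 0.1, 0.5), "negative")
  expect_lt(out, 0)
  expect_error(kjeldahl_nitrogen(10, 1, 0.1, 0), "dry mass")
})

test_that("split schemes produce disjoint exhaustive 60/30/10 partitions", {
  expect_error(split_scheme(0.5, 0.3, 0.1), "sum to 1")
  sch <- split_scheme(iterations = 2L, seed = 5L)
  sp <- nitrospec:::split_indices(100L, sch, 9L)
  expect_length(sp$train, 60L)
  expect_length(sp$test, 30L)
  expect_length(sp$validation, 10L)
  expect_equal(sort(c(sp$train, sp$test, sp$validation)), 1:100)
})

test_that("repeated evaluation pools confusion counts conservatively", {
  d <- generate_dataset(small_config(n = 25L))
  pre <- preprocess_dataset(d)
  band <- function(nm) which.min(abs(pre$wavelengths - nm))
  red <- subset_samples(pre, seq_len(n_samples(pre)))
  red$spectra <- red$spectra[, c(band(723), band(781), band(901))]
  red$wavelengths <- red$wavelengths[c(band(723), band(781), band(901))]

  fast <- ensemble_config(ann_population = 8L, ann_generations = 2L,
                          hs_memory = 6L, hs_improvisations = 30L,
                          inner_epochs = 25L)
  one <- repeated_evaluation(red, split_scheme(iterations = 1L, seed = 3L),
                             fast)
  expect_equal(sum(one$confusions$MV), 30L)  # one 30% test split of 100
  expect_equal(unname(rowSums(one$confusions$MV)),
               unname(rowSums(one$confusions$KNN)))

  three <- repeated_evaluation(red, split_scheme(iterations = 3L, seed = 3L),
                               fast)
  expect_equal(sum(three$confusions$MV), 3L * 30L)
  expect_equal(dim(three$ccr_series), c(3L, 6L))
  expect_false(anyNA(three$auc_series))
  # iteration 1 of the same scheme seed is reproduced exactly
  expect_equal(one$ccr_series[1L, ], three$ccr_series[1L, ])
})
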