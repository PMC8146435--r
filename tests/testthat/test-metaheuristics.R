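# shared index-subset benchmark: alignment distance to the target triple
# {3, 6, 10} out of 20 items; the global optimum (cost 0) is verified by
# exhaustive enumeration in the acceptance suite
subset_benchmark <- function(target = c(3L, 6L, 10L), n_items = 20L) {
  objective_subset(function(idx) sum(abs(sort(idx) - target)), n_items,
                   length(target))
}

test_that("zero-generation BBO returns the best of the initial population", {
  obj <- objective_continuous(function(x) sum(x^2), -5, 5, dim = 3)
  res <- bbo_optimize(obj, bbo_params(population = 10L, generations = 0L,
                                      seed = 4L))
  expect_length(res$history, 1L)
  # oracle: regenerate the same initial population directly
  set.seed(4L)
  pop <- replicate(10, runif(3, -5, 5), simplify = FALSE)
  expect_equal(res$best$cost, min(vapply(pop, function(x) sum(x^2), 0)))
})

test_that("all three optimizers are monotone, deterministic and honest", {
  obj <- objective_continuous(function(x) sum((x - 1)^2), -5, 5, dim = 2)
  runs <- list(
    bbo = function(s) bbo_optimize(obj, bbo_params(population = 12L,
      generations = 15L, seed = s)),
    ica = function(s) ica_optimize(obj, ica_params(population = 12L,
      generations = 15L, n_imperialists = 3L, seed = s)),
    hs = function(s) hs_optimize(obj, hs_params(memory_size = 8L,
      improvisations = 80L, seed = s))
  )
  for (nm in names(runs)) {
    for (s in c(1L, 9L)) {
      r1 <- runs[[nm]](s)
      # best-so-far non-increasing
      expect_true(all(diff(r1$history) <= 1e-12), label = nm)
      # no stale caching: reported cost equals re-evaluation
      expect_equal(r1$best$cost, obj$evaluate(r1$best$siv))
      # reproducible under the same seed
      r2 <- runs[[nm]](s)
      expect_identical(r1$best, r2$best)
      expect_identical(r1$history, r2$history)
    }
  }
})

test_that("BBO recovers a planted index subset", {
  obj <- subset_benchmark()
  res <- bbo_optimize(obj, bbo_params(population = 30L, generations = 60L,
                                      seed = 1L))
  expect_identical(sort(res$best$siv), c(3L, 6L, 10L))
  expect_equal(res$best$cost, 0)
})

test_that("ICA solves the 2-D sphere to high precision", {
  obj <- objective_continuous(function(x) sum(x^2), -5, 5, dim = 2)
  res <- ica_optimize(obj, ica_params(population = 40L, generations = 100L,
                                      n_imperialists = 5L, seed = 3L))
  expect_lt(res$best$cost, 1e-2)
})

test_that("a degenerate ICA population stays constant without revolutions", {
  # all countries effectively at one point, no revolutions: assimilation
  # cannot move anyone, so the best cost never changes
  obj <- objective_continuous(function(x) sum((x - 5)^2), 5, 5 + 1e-12,
                              dim = 2)
  res <- ica_optimize(obj, ica_params(population = 8L, generations = 10L,
                                      n_imperialists = 2L,
                                      revolution_rate = 0, seed = 2L))
  expect_equal(diff(res$history), rep(0, 10L), tolerance = 1e-20)
})

test_that("ICA enforces its population/imperialist precondition", {
  expect_error(ica_params(population = 6L, n_imperialists = 4L),
               "n_imperialists")
})

test_that("harmony search finds a 1-D quadratic minimum", {
  obj <- objective_continuous(function(x) (x - 2)^2, 0, 10, dim = 1)
  res <- hs_optimize(obj, hs_params(memory_size = 10L,
                                    improvisations = 500L, seed = 5L))
  expect_lt(abs(res$best$siv - 2), 0.05)
})

test_that("memory-free harmony search is a monotone pure random search", {
  obj <- objective_continuous(function(x) sum(x^2), -3, 3, dim = 2)
  res <- hs_optimize(obj, hs_params(memory_size = 5L, improvisations = 60L,
                                    memory_consider_rate = 0, seed = 7L))
  expect_true(all(diff(res$history) <= 0))
})

test_that("pitch adjustment with zero bandwidth cannot degrade the memory", {
  # HMCR 1 and bandwidth 0 only ever replay memory entries, so the best
  # memory cost is frozen at its initial value
  obj <- objective_continuous(function(x) sum(x^2), -3, 3, dim = 2)
  res <- hs_optimize(obj, hs_params(memory_size = 6L, improvisations = 50L,
                                    memory_consider_rate = 1,
                                    pitch_adjust_rate = 1, bandwidth = 0,
                                    seed = 1L))
  expect_equal(res$history, rep(res$history[1L], 51L))
})

test_that("non-finite objective values are reported with context", {
  obj <- objective_continuous(function(x) NaN, -1, 1, dim = 1)
  expect_error(bbo_optimize(obj, bbo_params(population = 4L,
                                            generations = 1L)),
               "non-finite")
})
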