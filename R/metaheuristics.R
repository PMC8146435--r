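## Population metaheuristics over a shared objective contract.
##
## Two solution encodings are supported:
##  * continuous  - real vector within per-dimension box bounds
##  * index_subset - fixed-length vector of distinct integer indices in
##    1..n_items (used for wavelength-subset search); duplicates created by
##    any move are repaired by resampling.
## All optimizers minimize; costs must be finite and deterministic given a
## solution (stochastic objectives should fix their own internal seed).

#' Continuous objective
#'
#' @param fn Function mapping a numeric solution vector to a finite scalar
#'   cost (lower is better).
#' @param lower,upper Finite per-dimension bounds (recycled to `dim`).
#' @param dim Number of dimensions (>= 1).
#' @return An `objective` object.
#' @export
objective_continuous <- function(fn, lower, upper, dim = length(lower)) {
  lower <- rep_len(as.numeric(lower), dim)
  upper <- rep_len(as.numeric(upper), dim)
  stopifnot(dim >= 1L, all(is.finite(lower)), all(is.finite(upper)),
            all(lower < upper))
  structure(list(evaluate = fn, lower = lower, upper = upper, dim = dim,
                 encoding = "continuous"),
            class = "objective")
}

#' Index-subset objective
#'
#' Solutions are vectors of `subset_size` distinct indices in
#' `1..n_items`; `fn` receives the (unsorted) index vector.
#'
#' @param fn Cost function over an index vector.
#' @param n_items Number of selectable items.
#' @param subset_size Number of indices per solution.
#' @return An `objective` object.
#' @export
objective_subset <- function(fn, n_items, subset_size) {
  stopifnot(subset_size >= 1L, n_items >= subset_size)
  structure(list(evaluate = fn, lower = rep(1, subset_size),
                 upper = rep(n_items, subset_size), dim = subset_size,
                 n_items = as.integer(n_items), encoding = "index_subset"),
            class = "objective")
}

obj_random <- function(obj) {
  if (obj$encoding == "index_subset") sort(sample.int(obj$n_items, obj$dim))
  else runif(obj$dim, obj$lower, obj$upper)
}

## clamp/round and resolve duplicate indices by resampling; index subsets
## are kept in canonical ascending order so that the same solution has one
## representation and position k means "k-th lowest index" in every
## habitat/harmony -- positionwise exchanges between solutions then swap
## like with like instead of scrambling unrelated variables
obj_repair <- function(obj, x) {
  if (obj$encoding == "continuous")
    return(pmin(pmax(x, obj$lower), obj$upper))
  x <- as.integer(pmin(pmax(round(x), 1L), obj$n_items))
  dup <- duplicated(x)
  while (any(dup)) {
    x[dup] <- sample.int(obj$n_items, sum(dup))
    dup <- duplicated(x)
  }
  sort(x)
}

## fresh value for a single position; for subsets, half the moves are local
## (+/- 1..3 grid steps) so band positions can be refined, half are global
obj_mutate_pos <- function(obj, x, j) {
  if (obj$encoding == "continuous") {
    x[j] <- runif(1L, obj$lower[j], obj$upper[j])
  } else if (runif(1L) < 0.5) {
    x[j] <- x[j] + sample(c(-3L, -2L, -1L, 1L, 2L, 3L), 1L)
  } else {
    x[j] <- sample.int(obj$n_items, 1L)
  }
  obj_repair(obj, x)
}

eval_cost <- function(obj, x) {
  v <- obj$evaluate(x)
  if (!is.finite(v))
    stop("objective returned a non-finite cost for solution [",
         paste(signif(x, 4), collapse = ", "), "]", call. = FALSE)
  v
}

#' Biogeography-based optimization parameters
#'
#' Defaults follow the algorithm's original formulation: immigration and
#' emigration scale linearly with fitness rank, small per-variable mutation,
#' two elites.
#'
#' @param population Number of habitats.
#' @param generations Number of migration generations.
#' @param seed RNG seed.
#' @param mutation_prob Per-variable mutation probability.
#' @param elitism_count Habitats preserved unchanged each generation.
#' @param max_immigration,max_emigration Maximum immigration rate I and
#'   emigration rate E.
#' @return Parameter list of class `bbo_params`.
#' @export
bbo_params <- function(population = 30L, generations = 50L, seed = 1L,
                       mutation_prob = 0.05, elitism_count = 2L,
                       max_immigration = 1, max_emigration = 1) {
  stopifnot(population >= 1L, generations >= 0L,
            mutation_prob >= 0, mutation_prob <= 1,
            max_immigration >= 0, max_immigration <= 1,
            max_emigration >= 0, max_emigration <= 1)
  if (elitism_count > population)
    stop("elitism_count cannot exceed the population size", call. = FALSE)
  structure(list(population = as.integer(population),
                 generations = as.integer(generations),
                 seed = as.integer(seed), mutation_prob = mutation_prob,
                 elitism_count = as.integer(elitism_count),
                 max_immigration = max_immigration,
                 max_emigration = max_emigration),
            class = "bbo_params")
}

#' Biogeography-based optimization
#'
#' Habitats (candidate solutions) exchange suitability index variables by
#' rank-based migration: with habitats ranked `k = 0` (best) to `n - 1`,
#' the immigration rate is `I * k / (n - 1)` and the emigration rate
#' `E * (1 - k / (n - 1))`. Each immigrating position receives the value of
#' a donor habitat drawn with probability proportional to its emigration
#' rate; positions then mutate with probability `mutation_prob`. The best
#' `elitism_count` habitats survive each generation unchanged, so the
#' best-so-far cost is non-increasing.
#'
#' @param objective An [objective_continuous()] or [objective_subset()].
#' @param params A [bbo_params()].
#' @return List with `best` (list `siv`, `cost`), `history` (best cost per
#'   generation, length `generations + 1`) and `evaluations`.
#' @export
bbo_optimize <- function(objective, params = bbo_params()) {
  stopifnot(inherits(objective, "objective"), inherits(params, "bbo_params"))
  set.seed(params$seed)
  n <- params$population
  pop <- lapply(seq_len(n), function(i) obj_random(objective))
  cost <- vapply(pop, function(x) eval_cost(objective, x), numeric(1L))
  evals <- n
  ord <- order(cost)
  pop <- pop[ord]; cost <- cost[ord]
  history <- cost[1L]

  if (params$generations > 0L) {
    rank0 <- seq_len(n) - 1L
    denom <- max(n - 1L, 1L)
    lambda <- params$max_immigration * rank0 / denom
    mu <- params$max_emigration * (1 - rank0 / denom)
    for (g in seq_len(params$generations)) {
      newpop <- pop
      for (k in seq_len(n)) {
        if (k <= params$elitism_count) next
        x <- pop[[k]]
        for (j in seq_len(objective$dim)) {
          if (runif(1L) < lambda[k]) {
            donor <- if (sum(mu) > 0) sample.int(n, 1L, prob = mu)
                     else sample.int(n, 1L)
            x[j] <- pop[[donor]][j]
          }
        }
        for (j in seq_len(objective$dim))
          if (runif(1L) < params$mutation_prob)
            x <- obj_mutate_pos(objective, x, j)
        newpop[[k]] <- obj_repair(objective, x)
      }
      newcost <- cost
      changed <- which(!vapply(seq_len(n), function(k)
        identical(newpop[[k]], pop[[k]]), logical(1L)))
      for (k in changed) {
        newcost[k] <- eval_cost(objective, newpop[[k]])
        evals <- evals + 1L
      }
      ord <- order(newcost)
      pop <- newpop[ord]; cost <- newcost[ord]
      history <- c(history, cost[1L])
    }
  }
  list(best = list(siv = pop[[1L]], cost = cost[1L]),
       history = history, evaluations = evals)
}

#' Imperialist competitive algorithm parameters
#'
#' @param population Total number of countries.
#' @param generations Number of decades (epochs).
#' @param seed RNG seed.
#' @param n_imperialists Number of empires (must satisfy
#'   `population - n_imperialists >= n_imperialists`).
#' @param assimilation_beta Assimilation coefficient: colonies move toward
#'   their imperialist by `U(0, beta)` of the difference per dimension.
#' @param revolution_rate Probability that a colony is re-randomized.
#' @param colony_power_weight Weight of the mean colony cost in an empire's
#'   total power.
#' @return Parameter list of class `ica_params`.
#' @export
ica_params <- function(population = 30L, generations = 50L, seed = 1L,
                       n_imperialists = 5L, assimilation_beta = 2,
                       revolution_rate = 0.3, colony_power_weight = 0.05) {
  stopifnot(population >= 2L, generations >= 0L, n_imperialists >= 1L,
            revolution_rate >= 0, revolution_rate <= 1,
            assimilation_beta > 0, colony_power_weight >= 0)
  if (population - n_imperialists < n_imperialists)
    stop("population minus n_imperialists must be >= n_imperialists",
         call. = FALSE)
  structure(list(population = as.integer(population),
                 generations = as.integer(generations),
                 seed = as.integer(seed),
                 n_imperialists = as.integer(n_imperialists),
                 assimilation_beta = assimilation_beta,
                 revolution_rate = revolution_rate,
                 colony_power_weight = colony_power_weight),
            class = "ica_params")
}

#' Imperialist competitive algorithm
#'
#' Random countries are split into imperialists (the best
#' `n_imperialists`) and colonies allocated proportionally to normalized
#' imperialist power. Each epoch: colonies assimilate (move toward their
#' imperialist by `U(0, beta)` of the per-dimension difference), may revolt
#' (re-randomize), and swap roles with their imperialist when better; the
#' weakest empire (total power = imperialist cost +
#' `colony_power_weight *` mean colony cost; lower is stronger) loses its
#' weakest colony to the winner of a power-based lottery, and empires left
#' without colonies collapse into the winner.
#'
#' @param objective An [objective_continuous()] or [objective_subset()].
#' @param params An [ica_params()].
#' @return List with `best` (list `siv`, `cost`), `history` (best cost per
#'   epoch) and `evaluations`.
#' @export
ica_optimize <- function(objective, params = ica_params()) {
  stopifnot(inherits(objective, "objective"), inherits(params, "ica_params"))
  set.seed(params$seed)
  n <- params$population
  nimp <- params$n_imperialists
  pop <- lapply(seq_len(n), function(i) obj_random(objective))
  cost <- vapply(pop, function(x) eval_cost(objective, x), numeric(1L))
  evals <- n
  ord <- order(cost)
  impX <- pop[ord[seq_len(nimp)]]
  impC <- cost[ord[seq_len(nimp)]]
  colX <- pop[ord[-seq_len(nimp)]]
  colC <- cost[ord[-seq_len(nimp)]]
  ncol_ <- length(colX)

  ## colony allocation proportional to normalized imperialist power
  power <- max(impC) - impC + 1e-12
  share <- power / sum(power)
  counts <- floor(share * ncol_)
  while (sum(counts) < ncol_) {
    i <- which.max(share * ncol_ - counts)
    counts[i] <- counts[i] + 1L
  }
  owner <- sample(rep.int(seq_len(nimp), counts))

  best_sol <- impX[[which.min(impC)]]
  best_cost <- min(impC)
  history <- best_cost

  for (epoch in seq_len(params$generations)) {
    for (i in seq_len(ncol_)) {
      k <- owner[i]
      x <- colX[[i]] +
        runif(objective$dim, 0, params$assimilation_beta) *
          (impX[[k]] - colX[[i]])
      if (runif(1L) < params$revolution_rate) x <- obj_random(objective)
      x <- obj_repair(objective, x)
      colX[[i]] <- x
      colC[i] <- eval_cost(objective, x)
      evals <- evals + 1L
      if (colC[i] < impC[k]) {
        tmp <- impX[[k]]; impX[[k]] <- colX[[i]]; colX[[i]] <- tmp
        tmpc <- impC[k]; impC[k] <- colC[i]; colC[i] <- tmpc
      }
    }
    ## imperialistic competition (needs at least two empires)
    alive <- sort(unique(c(seq_along(impC))))
    if (length(impC) > 1L) {
      total <- vapply(seq_along(impC), function(k) {
        mine <- which(owner == k)
        impC[k] + if (length(mine))
          params$colony_power_weight * mean(colC[mine]) else 0
      }, numeric(1L))
      weakest <- which.max(total)
      npower <- max(total) - total
      npower[weakest] <- 0
      prob <- if (sum(npower) > 0) npower / sum(npower)
              else {p <- rep(1, length(total)); p[weakest] <- 0; p / sum(p)}
      winner <- sample.int(length(total), 1L, prob = prob)
      mine <- which(owner == weakest)
      if (length(mine)) {
        lost <- mine[which.max(colC[mine])]
        owner[lost] <- winner
      } else {
        ## empire without colonies collapses: its imperialist becomes a
        ## colony of the winner
        colX <- c(colX, impX[weakest])
        colC <- c(colC, impC[weakest])
        owner <- c(owner, winner)
        ncol_ <- ncol_ + 1L
        impX <- impX[-weakest]; impC <- impC[-weakest]
        owner[owner > weakest] <- owner[owner > weakest] - 1L
      }
    }
    if (min(impC) < best_cost) {
      best_cost <- min(impC)
      best_sol <- impX[[which.min(impC)]]
    }
    history <- c(history, best_cost)
  }
  list(best = list(siv = best_sol, cost = best_cost),
       history = history, evaluations = evals)
}

#' Harmony search parameters
#'
#' @param memory_size Harmony memory size.
#' @param improvisations Number of new harmonies improvised.
#' @param seed RNG seed.
#' @param memory_consider_rate Probability a variable is drawn from memory
#'   (HMCR).
#' @param pitch_adjust_rate Probability a memory-drawn variable is pitch
#'   adjusted (PAR).
#' @param bandwidth Pitch-adjustment half-width. `NULL` defaults to 5% of
#'   each bound range (continuous) or 2 grid steps (index subsets).
#' @return Parameter list of class `hs_params`.
#' @export
hs_params <- function(memory_size = 20L, improvisations = 500L, seed = 1L,
                      memory_consider_rate = 0.9, pitch_adjust_rate = 0.3,
                      bandwidth = NULL) {
  stopifnot(memory_size >= 1L, improvisations >= 0L,
            memory_consider_rate >= 0, memory_consider_rate <= 1,
            pitch_adjust_rate >= 0, pitch_adjust_rate <= 1)
  structure(list(memory_size = as.integer(memory_size),
                 improvisations = as.integer(improvisations),
                 seed = as.integer(seed),
                 memory_consider_rate = memory_consider_rate,
                 pitch_adjust_rate = pitch_adjust_rate,
                 bandwidth = bandwidth),
            class = "hs_params")
}

#' Harmony search
#'
#' Each improvisation builds a new solution variable by variable: with
#' probability `memory_consider_rate` the value is copied from a random
#' harmony in memory (and then pitch-adjusted within `+/- bandwidth` with
#' probability `pitch_adjust_rate`), otherwise it is drawn uniformly from
#' the bounds. The new harmony replaces the worst memory entry when it is
#' better, so memory never worsens.
#'
#' @param objective An [objective_continuous()] or [objective_subset()].
#' @param params An [hs_params()].
#' @return List with `best` (list `siv`, `cost`), `history` (best cost after
#'   initialization and after each improvisation) and `evaluations`.
#' @export
hs_optimize <- function(objective, params = hs_params()) {
  stopifnot(inherits(objective, "objective"), inherits(params, "hs_params"))
  set.seed(params$seed)
  m <- params$memory_size
  bw <- params$bandwidth
  if (is.null(bw))
    bw <- if (objective$encoding == "index_subset") 2
          else 0.05 * (objective$upper - objective$lower)
  bw <- rep_len(bw, objective$dim)
  mem <- lapply(seq_len(m), function(i) obj_random(objective))
  memc <- vapply(mem, function(x) eval_cost(objective, x), numeric(1L))
  evals <- m
  history <- min(memc)
  for (it in seq_len(params$improvisations)) {
    x <- numeric(objective$dim)
    for (j in seq_len(objective$dim)) {
      if (runif(1L) < params$memory_consider_rate) {
        x[j] <- mem[[sample.int(m, 1L)]][j]
        if (runif(1L) < params$pitch_adjust_rate) {
          x[j] <- if (objective$encoding == "index_subset")
            x[j] + sample(c(-1L, 1L), 1L) * sample.int(max(1L, round(bw[j])), 1L)
          else x[j] + runif(1L, -bw[j], bw[j])
        }
      } else {
        x[j] <- if (objective$encoding == "index_subset")
          sample.int(objective$n_items, 1L)
        else runif(1L, objective$lower[j], objective$upper[j])
      }
    }
    x <- obj_repair(objective, x)
    cx <- eval_cost(objective, x)
    evals <- evals + 1L
    worst <- which.max(memc)
    if (cx < memc[worst]) {
      mem[[worst]] <- x
      memc[worst] <- cx
    }
    history <- c(history, min(memc))
  }
  b <- which.min(memc)
  list(best = list(siv = mem[[b]], cost = memc[b]),
       history = history, evaluations = evals)
}
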