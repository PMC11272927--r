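# Multi-objective Pareto-based evolutionary optimization: joint selection of
# the feature subset, the classifier family (random forest vs SVM) and its
# hyperparameters, under stratified cross-validation with in-fold class
# balancing.

.OBJECTIVE_NAMES <- c(
  "feat_min", "acc", "f1", "f2", "precision", "recall", "auc",
  "complexity_min", "manhattan"
)

#' Default nine-objective fitness weights
#'
#' Feature-count minimization 1, ACC 10, F1 10, F2 1, precision 1, recall 10,
#' AUC 1, model-complexity minimization 1, Manhattan distance 1 (maximum
#' attainable scalar fitness 36).
#' @return named numeric vector of weights
#' @export
fitness_weights <- function() {
  setNames(c(1, 10, 10, 1, 1, 10, 1, 1, 1), .OBJECTIVE_NAMES)
}

#' Evolutionary optimizer configuration
#'
#' Defaults follow the published protocol: population 100, 200 generations,
#' two-point crossover probability 0.9, per-gene mutation probability 0.01,
#' arithmetic crossover probability 0, ten independent runs.
#'
#' @param population_size individuals per generation
#' @param max_generations termination criterion
#' @param p_two_point_crossover two-point crossover probability
#' @param p_mutation per-gene mutation probability
#' @param p_arithmetic_crossover arithmetic (blend) crossover probability
#' @param n_runs independent repetitions for [evolve_runs()]
#' @param weights objective weights (see [fitness_weights()])
#' @param k cross-validation folds per evaluation
#' @param max_trees upper end of the random-forest tree-count gene
#' @param init_density expected fraction of features switched on at
#'   initialization
#' @param seed master RNG seed
#' @return an `EvoConfig` list
#' @export
evo_config <- function(population_size = 100L, max_generations = 200L,
                       p_two_point_crossover = 0.9, p_mutation = 0.01,
                       p_arithmetic_crossover = 0, n_runs = 10L,
                       weights = fitness_weights(), k = 10L,
                       max_trees = 200L, init_density = 0.1, seed = 1L) {
  tk_assert(population_size >= 2, "population_size must be >= 2")
  tk_assert(max_generations >= 1, "max_generations must be >= 1")
  probs <- c(p_two_point_crossover, p_mutation, p_arithmetic_crossover)
  tk_assert(all(probs >= 0 & probs <= 1), "probabilities must lie in [0,1]")
  tk_assert(all(weights >= 0), "weights must be non-negative")
  structure(
    list(
      population_size = as.integer(population_size),
      max_generations = as.integer(max_generations),
      p_two_point_crossover = p_two_point_crossover,
      p_mutation = p_mutation,
      p_arithmetic_crossover = p_arithmetic_crossover,
      n_runs = as.integer(n_runs), weights = weights, k = as.integer(k),
      max_trees = as.integer(max_trees), init_density = init_density,
      seed = as.integer(seed)
    ),
    class = "EvoConfig"
  )
}

# Genome = feature mask bits ++ family bit ++ two real-coded hyperparameter
# genes in [0,1]. Two-point crossover and mutation act on the whole genome.
new_individual <- function(m, density) {
  mask <- runif(m) < density
  if (!any(mask)) mask[sample.int(m, 1)] <- TRUE
  list(mask = mask, family = sample(c(1L, 2L), 1), hp = runif(2))
}

decode_spec <- function(ind, config, seed = 1L) {
  if (ind$family == 1L) {
    classifier_spec("random_forest",
      n_trees = as.integer(round(10 + ind$hp[1] * (config$max_trees - 10))),
      seed = seed
    )
  } else {
    classifier_spec("svm",
      C = 10^(-3 + 6 * ind$hp[1]), gamma = 10^(-3 + 6 * ind$hp[2]),
      seed = seed
    )
  }
}

genome_key <- function(ind) {
  paste(
    paste(as.integer(ind$mask), collapse = ""), ind$family,
    paste(round(ind$hp, 6), collapse = ","),
    sep = "|"
  )
}

#' Evaluate an individual's nine objectives
#'
#' Runs stratified k-fold cross-validation on the masked feature set and maps
#' the results to the nine maximization objectives: minimization objectives
#' (feature count, number of trees / support vectors) are rescaled to
#' `1 - count/maximum`. An empty mask is repaired (one random bit set) before
#' evaluation.
#'
#' @param ind individual (mask, family, hp)
#' @param X normalized feature matrix over all candidate features
#' @param y class labels
#' @param config an [evo_config()]
#' @param eval_seed seed for the embedded cross-validation
#' @return list with `objectives` (length-9 vector), `cv`, and the possibly
#'   repaired individual
#' @export
evaluate_individual <- function(ind, X, y, config = evo_config(), eval_seed = 1L) {
  if (!any(ind$mask)) {
    ind$mask[sample.int(length(ind$mask), 1)] <- TRUE
    ind$repaired <- TRUE
  }
  m <- ncol(X)
  spec <- decode_spec(ind, config, seed = eval_seed)
  cv <- cross_validate(spec, X[, ind$mask, drop = FALSE], y,
    k = config$k, seed = eval_seed
  )
  max_complex <- if (ind$family == 1L) config$max_trees else length(y)
  obj <- setNames(c(
    1 - sum(ind$mask) / m,
    cv$mean[c("acc", "f1", "f2", "precision", "recall", "auc")],
    1 - min(cv$complexity / max_complex, 1),
    cv$distance_term
  ), .OBJECTIVE_NAMES)
  ind$objectives <- obj
  ind$cv <- cv
  list(objectives = obj, cv = cv, individual = ind)
}

#' Weighted scalar fitness
#'
#' @param objectives length-9 vector of objectives in [0,1]
#' @param weights matching weight vector
#' @return weighted sum (36 at the optimum under default weights)
#' @export
scalar_fitness <- function(objectives, weights = fitness_weights()) {
  tk_assert(length(objectives) == length(weights), "objective/weight length mismatch")
  sum(objectives * weights)
}

#' Pareto front of an evaluated population
#'
#' An individual is dominated if another is at least as good in every
#' objective and strictly better in at least one; ties (identical objective
#' vectors) are all retained.
#'
#' @param objectives matrix (individuals x objectives)
#' @return logical vector marking front members
#' @export
pareto_front <- function(objectives) {
  n <- nrow(objectives)
  nd <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (all(objectives[j, ] >= objectives[i, ]) &&
        any(objectives[j, ] > objectives[i, ])) {
        nd[i] <- FALSE
        break
      }
    }
  }
  nd
}

.mutate <- function(ind, p) {
  m <- length(ind$mask)
  flip <- runif(m) < p
  ind$mask[flip] <- !ind$mask[flip]
  if (runif(1) < p) ind$family <- 3L - ind$family
  for (h in 1:2) {
    if (runif(1) < p) ind$hp[h] <- min(max(ind$hp[h] + rnorm(1, 0, 0.15), 0), 1)
  }
  if (!any(ind$mask)) ind$mask[sample.int(m, 1)] <- TRUE
  ind
}

# Two-point crossover on the concatenated genome (mask ++ family ++ hp).
.crossover <- function(a, b) {
  m <- length(a$mask)
  ga <- c(as.numeric(a$mask), a$family, a$hp)
  gb <- c(as.numeric(b$mask), b$family, b$hp)
  L <- length(ga)
  pts <- sort(sample.int(L - 1, 2))
  seg <- (pts[1] + 1):pts[2]
  tmp <- ga[seg]; ga[seg] <- gb[seg]; gb[seg] <- tmp
  unpack <- function(g) {
    list(
      mask = g[1:m] > 0.5, family = as.integer(round(g[m + 1])),
      hp = pmin(pmax(g[(m + 2):(m + 3)], 0), 1)
    )
  }
  list(unpack(ga), unpack(gb))
}

.tournament <- function(fit, rank) {
  i <- sample.int(length(fit), 2)
  a <- i[1]; b <- i[2]
  if (abs(fit[a] - fit[b]) > 1e-12) {
    if (fit[a] > fit[b]) a else b
  } else if (rank[a] != rank[b]) {
    if (rank[a] < rank[b]) a else b
  } else if (runif(1) < 0.5) {
    a
  } else {
    b
  }
}

#' Run the evolutionary optimization
#'
#' Generational loop with size-2 tournament selection on scalar fitness
#' (Pareto-rank tie-break), two-point crossover, per-gene mutation, and
#' elitism preserving the current Pareto front. The per-generation history
#' records best and mean fitness and a convergence flag (mean within 5% of
#' the best) — diagnostic only; the stopping rule is `max_generations`.
#'
#' @param X normalized feature matrix of candidate (screened) features
#' @param y class labels
#' @param config an [evo_config()]
#' @param verbose print per-generation progress
#' @return list: `front` (evaluated non-dominated individuals), `history`
#'   data.frame, `best` (highest scalar fitness individual), `config`
#' @export
evolve <- function(X, y, config = evo_config(), verbose = FALSE) {
  X <- as.matrix(X)
  tk_assert(ncol(X) >= 1, "no candidate features")
  m <- ncol(X)
  set.seed(config$seed)
  eval_seed <- derive_seed(config$seed, 977L)
  cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  eval_cached <- function(ind) {
    key <- genome_key(ind)
    hit <- get0(key, envir = cache)
    if (!is.null(hit)) {
      ind$objectives <- hit$objectives
      ind$cv <- hit$cv
      return(ind)
    }
    res <- evaluate_individual(ind, X, y, config, eval_seed = eval_seed)
    n_eval <<- n_eval + 1L
    assign(key, res, envir = cache)
    res$individual
  }

  pop <- lapply(seq_len(config$population_size), function(i) {
    new_individual(m, config$init_density)
  })
  pop <- lapply(pop, eval_cached)
  history <- data.frame()
  for (gen in seq_len(config$max_generations)) {
    objs <- do.call(rbind, lapply(pop, `[[`, "objectives"))
    fit <- apply(objs, 1, scalar_fitness, weights = config$weights)
    front_mask <- pareto_front(objs)
    rank <- ifelse(front_mask, 1L, 2L)
    best <- max(fit); avg <- mean(fit)
    history <- rbind(history, data.frame(
      generation = gen, best_fitness = best, mean_fitness = avg,
      front_size = sum(front_mask),
      converged = (best - avg) / best < 0.05
    ))
    if (verbose) {
      message(sprintf("gen %3d  best %.3f  mean %.3f  front %d  evals %d",
        gen, best, avg, sum(front_mask), n_eval))
    }
    if (gen == config$max_generations) break
    # elitism: carry the current Pareto front, deduplicated by genome and
    # trimmed to a third of the population by scalar fitness if oversized
    # (carrying clones would collapse population diversity)
    elite_idx <- which(front_mask)
    elite_idx <- elite_idx[!duplicated(vapply(pop[elite_idx], genome_key, ""))]
    if (length(elite_idx) > config$population_size / 3) {
      elite_idx <- elite_idx[order(fit[elite_idx], decreasing = TRUE)]
      elite_idx <- elite_idx[seq_len(config$population_size %/% 3)]
    }
    nextgen <- pop[elite_idx]
    seen <- new.env(parent = emptyenv())
    for (e in nextgen) assign(genome_key(e), TRUE, envir = seen)
    varying <- config$p_mutation > 0 || config$p_two_point_crossover > 0 ||
      config$p_arithmetic_crossover > 0
    while (length(nextgen) < config$population_size) {
      pa <- pop[[.tournament(fit, rank)]]
      pb <- pop[[.tournament(fit, rank)]]
      if (runif(1) < config$p_two_point_crossover) {
        ch <- .crossover(pa, pb)
      } else if (runif(1) < config$p_arithmetic_crossover) {
        lam <- runif(1)
        child <- pa
        child$hp <- lam * pa$hp + (1 - lam) * pb$hp
        ch <- list(child, pb)
      } else {
        ch <- list(pa, pb)
      }
      for (child in ch) {
        if (length(nextgen) >= config$population_size) break
        child <- .mutate(child[c("mask", "family", "hp")], config$p_mutation)
        # duplicate avoidance: a child genome already present this generation
        # gets one extra random bit-flip to preserve search diversity
        if (varying && !is.null(get0(genome_key(child), envir = seen))) {
          flip <- sample.int(length(child$mask), 1)
          child$mask[flip] <- !child$mask[flip]
          if (!any(child$mask)) child$mask[flip] <- TRUE
        }
        assign(genome_key(child), TRUE, envir = seen)
        nextgen[[length(nextgen) + 1]] <- eval_cached(child)
      }
    }
    pop <- nextgen
  }
  objs <- do.call(rbind, lapply(pop, `[[`, "objectives"))
  front_mask <- pareto_front(objs)
  front <- pop[front_mask]
  fit <- apply(objs[front_mask, , drop = FALSE], 1, scalar_fitness,
    weights = config$weights)
  list(
    front = front, history = history,
    best = front[[which.max(fit)]],
    population = pop,
    n_evaluations = n_eval, config = config
  )
}

#' Select the final model from a Pareto front
#'
#' @param front list of evaluated individuals (from [evolve()])
#' @param preference `knee` (maximum scalar fitness, ties broken toward fewer
#'   features), `fewest_features`, `max_accuracy`, or an explicit index
#' @param weights objective weights for the knee criterion
#' @return the chosen individual
#' @export
select_final <- function(front, preference = "knee", weights = fitness_weights()) {
  tk_assert(length(front) > 0, "empty Pareto front")
  nfeat <- vapply(front, function(i) sum(i$mask), numeric(1))
  if (is.numeric(preference)) {
    tk_assert(preference >= 1 && preference <= length(front), "index out of range")
    return(front[[preference]])
  }
  if (preference == "fewest_features") return(front[[which.min(nfeat)]])
  if (preference == "max_accuracy") {
    accs <- vapply(front, function(i) i$objectives[["acc"]], numeric(1))
    return(front[[which.max(accs)]])
  }
  fit <- vapply(front, function(i) scalar_fitness(i$objectives, weights), numeric(1))
  best <- which(abs(fit - max(fit)) < 1e-12)
  if (length(best) > 1) best <- best[which.min(nfeat[best])]
  front[[best[1]]]
}

#' Repeat the optimization over independent runs
#'
#' Runs [evolve()] `config$n_runs` times with derived seeds and reports the
#' per-run selected model plus the mean and standard deviation of each CV
#' metric across runs (the protocol's multi-run aggregate).
#'
#' @inheritParams evolve
#' @return list: `runs` (list of evolve results), `selected` (per-run chosen
#'   individual), `aggregate` (mean/sd of CV metrics over runs)
#' @export
evolve_runs <- function(X, y, config = evo_config(), verbose = FALSE) {
  runs <- vector("list", config$n_runs)
  chosen <- vector("list", config$n_runs)
  for (r in seq_len(config$n_runs)) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, 5000L + r)
    runs[[r]] <- evolve(X, y, cfg, verbose = verbose)
    chosen[[r]] <- select_final(runs[[r]]$front, weights = config$weights)
  }
  mets <- do.call(rbind, lapply(chosen, function(i) {
    i$cv$mean[c("acc", "f1", "f2", "precision", "recall", "auc")]
  }))
  list(
    runs = runs, selected = chosen,
    aggregate = list(mean = colMeans(mets), sd = apply(mets, 2, sd))
  )
}
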