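# Evolutionary multi-objective model construction.

test_that("scalar fitness is the weighted sum with maximum 36", {
  w <- fitness_weights()
  expect_length(w, 9)
  expect_equal(scalar_fitness(rep(1, 9), w), 36)
  expect_equal(scalar_fitness(rep(0, 9), w), 0)
  obj <- runif(9)
  expect_equal(scalar_fitness(obj, 2 * w), 2 * scalar_fitness(obj, w))
  expect_error(scalar_fitness(rep(1, 5), w), "mismatch")
})

test_that("pareto front matches brute-force dominance on toys", {
  toy <- rbind(c(1, 0), c(0, 1), c(0.5, 0.5), c(0.4, 0.4))
  expect_equal(pareto_front(toy), c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(pareto_front(matrix(c(0.3, 0.7), 1)), TRUE)
  # duplicated objective vectors are all retained
  dup <- rbind(c(0.5, 0.5), c(0.5, 0.5), c(0.2, 0.2))
  expect_equal(pareto_front(dup), c(TRUE, TRUE, FALSE))
})

test_that("evaluation produces nine objectives and matches a direct CV run", {
  sep <- make_separable(n_per_class = 15, n_features = 10, n_informative = 4, shift = 2)
  cfg <- evo_config(population_size = 4, max_generations = 2, k = 3, seed = 5,
    max_trees = 50)
  ind <- list(mask = c(rep(TRUE, 4), rep(FALSE, 6)), family = 1L, hp = c(0.5, 0.5))
  ev <- evaluate_individual(ind, sep$X, sep$y, cfg, eval_seed = 77)
  expect_length(ev$objectives, 9)
  expect_true(all(ev$objectives >= 0 & ev$objectives <= 1))
  expect_equal(ev$objectives[["feat_min"]], 1 - 4 / 10)
  # re-computation oracle: same spec, mask and seed through cross_validate
  spec <- tastekit:::decode_spec(ind, cfg, seed = 77)
  cv <- cross_validate(spec, sep$X[, ind$mask], sep$y, k = 3, seed = 77)
  expect_equal(ev$cv$mean, cv$mean, tolerance = 1e-12)
  # all-features and single-feature endpoints of the feature objective
  indall <- list(mask = rep(TRUE, 10), family = 1L, hp = c(0.2, 0.2))
  expect_equal(
    evaluate_individual(indall, sep$X, sep$y, cfg, eval_seed = 1)$objectives[["feat_min"]], 0
  )
  ind1 <- list(mask = c(TRUE, rep(FALSE, 9)), family = 1L, hp = c(0.2, 0.2))
  expect_equal(
    evaluate_individual(ind1, sep$X, sep$y, cfg, eval_seed = 1)$objectives[["feat_min"]],
    1 - 1 / 10
  )
})

test_that("the optimizer is deterministic, elitist and front-consistent", {
  sep <- make_separable(n_per_class = 12, n_features = 12, n_informative = 4, shift = 2.5)
  cfg <- evo_config(population_size = 10, max_generations = 6, k = 3, seed = 17,
    max_trees = 40)
  r1 <- evolve(sep$X, sep$y, cfg)
  r2 <- evolve(sep$X, sep$y, cfg)
  expect_identical(
    lapply(r1$front, function(i) tastekit:::genome_key(i)),
    lapply(r2$front, function(i) tastekit:::genome_key(i))
  )
  # elitism: best scalar fitness never decreases
  expect_true(all(diff(r1$history$best_fitness) >= -1e-9))
  # front members are pairwise non-dominated (brute force)
  objs <- do.call(rbind, lapply(r1$front, `[[`, "objectives"))
  for (i in seq_len(nrow(objs))) {
    for (j in seq_len(nrow(objs))) {
      if (i == j) next
      expect_false(all(objs[j, ] >= objs[i, ]) && any(objs[j, ] > objs[i, ]))
    }
  }
})

test_that("without variation operators no new genomes enter the population", {
  sep <- make_separable(n_per_class = 10, n_features = 8, n_informative = 3, shift = 2)
  cfg <- evo_config(population_size = 8, max_generations = 4, k = 3, seed = 23,
    p_two_point_crossover = 0, p_mutation = 0, max_trees = 30)
  res <- evolve(sep$X, sep$y, cfg)
  expect_equal(length(unique(res$history$best_fitness)), 1)
  # every final genome already existed at initialization (selection only
  # reshuffles copies)
  set.seed(cfg$seed)
  init <- lapply(seq_len(cfg$population_size), function(i) {
    tastekit:::new_individual(8, cfg$init_density)
  })
  init_keys <- vapply(init, tastekit:::genome_key, "")
  final_keys <- vapply(res$population, tastekit:::genome_key, "")
  expect_true(all(final_keys %in% init_keys))
})

test_that("final-model selection honours preference and tie-breaks", {
  mk <- function(nfeat, acc, m = 6) {
    obj <- setNames(c(1 - nfeat / m, acc, acc, acc, acc, acc, acc, 0.5, 0.5),
      tastekit:::.OBJECTIVE_NAMES)
    list(mask = c(rep(TRUE, nfeat), rep(FALSE, m - nfeat)), family = 1L,
      hp = c(0.5, 0.5), objectives = obj)
  }
  single <- list(mk(2, 0.9))
  expect_identical(select_final(single), single[[1]])
  # dominant scalar fitness wins
  front <- list(mk(3, 0.95), mk(3, 0.6))
  expect_identical(select_final(front), front[[1]])
  # exact fitness tie: fewer features wins
  # performance-weight mass is 33, the feature objective differs by 1/3
  tie <- list(mk(4, 0.8), mk(2, 0.8 - (1 / 3) / 33))
  fit <- vapply(tie, function(i) scalar_fitness(i$objectives), numeric(1))
  expect_equal(fit[1], fit[2], tolerance = 1e-12)
  expect_identical(select_final(tie), tie[[2]])
  expect_identical(select_final(front, preference = "fewest_features"), front[[1]])
  expect_identical(select_final(front, preference = 2), front[[2]])
  expect_error(select_final(list()), "empty")
})
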