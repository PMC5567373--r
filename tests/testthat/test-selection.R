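test_that("ridge LOO fitness equals an explicit refit loop", {
  toy <- toy_regression(n = 15, k = 4)
  lam <- 1e-6
  for (subset in list("V1", c("V1", "V2"), c("V1", "V2", "V3", "V4"))) {
    oracle_pred <- bf_loo_pred(
      toy$X[, subset, drop = FALSE], toy$y,
      fit_fun = function(X, y) {
        X1 <- cbind(1, X)
        solve(crossprod(X1) + diag(c(0, rep(lam, ncol(X))), ncol(X1)),
              crossprod(X1, y))
      },
      pred_fun = function(beta, x) as.numeric(cbind(1, x) %*% beta))
    expect_equal(
      fitness_loo_rmse(subset, toy$X, toy$y,
                       fitness_regressor("ridge", lambda = lam)),
      sqrt(mean((toy$y - oracle_pred)^2)), tolerance = 1e-8)
  }
})

test_that("svr LOO fitness equals an explicit refit loop", {
  toy <- toy_regression(n = 12, k = 3)
  cfg <- svr_config(gamma = 0.1, epsilon = 0.1, cost = 10)
  oracle_pred <- bf_loo_pred(
    toy$X[, c("V1", "V2"), drop = FALSE], toy$y,
    fit_fun = function(X, y) svr_fit(X, y, cfg),
    pred_fun = function(m, x) predict(m, x))
  expect_equal(
    fitness_loo_rmse(c("V1", "V2"), toy$X, toy$y,
                     fitness_regressor("svr", svr = cfg)),
    sqrt(mean((toy$y - oracle_pred)^2)), tolerance = 1e-10)
})

test_that("fitness ordering of competing subsets matches the oracle", {
  toy <- toy_regression(n = 20, k = 4, noise = 0.2)
  f_good <- fitness_loo_rmse(c("V1", "V2"), toy$X, toy$y)
  f_bad <- fitness_loo_rmse(c("V3", "V4"), toy$X, toy$y)
  expect_lt(f_good, f_bad)  # the generating columns must win
  expect_error(fitness_loo_rmse(character(0), toy$X, toy$y), "empty")
  expect_error(fitness_loo_rmse("nope", toy$X, toy$y), "unknown")
  expect_error(fitness_loo_rmse("V1", toy$X[1:2, ], toy$y[1:2]), "at least 3")
})

test_that("ga_round is seeded-deterministic with a non-increasing best trace", {
  toy <- toy_regression(n = 30, k = 8, noise = 0.2)
  cfg <- ga_config(population_size = 12, generations = 10, seed = 7)
  r1 <- ga_round(colnames(toy$X), toy$X, toy$y, cfg)
  r2 <- ga_round(colnames(toy$X), toy$X, toy$y, cfg)
  expect_identical(r1$members, r2$members)
  expect_identical(r1$fitness_rmse, r2$fitness_rmse)
  expect_true(all(diff(r1$history) <= 0))
  expect_error(ga_round("V1", toy$X, toy$y, cfg), "at least 2")
})

test_that("without variation operators a uniform population is returned as-is", {
  toy <- toy_regression(n = 20, k = 5)
  chrom <- matrix(c(1L, 0L, 1L, 0L, 0L), 1)
  cfg <- ga_config(population_size = 6, generations = 5, mutation_rate = 0,
                   crossover_rate = 0, seed = 1)
  r <- ga_round(colnames(toy$X), toy$X, toy$y, cfg, init_population = chrom)
  expect_setequal(r$members, c("V1", "V3"))
})

test_that("chained GA rounds shrink the pool through the previous subset", {
  set.seed(31)
  n <- 60
  X <- matrix(rnorm(n * 20), n, 20,
              dimnames = list(NULL, sprintf("V%02d", 1:20)))
  y <- X[, 1] + 0.8 * X[, 2] + rnorm(n, 0, 0.2)
  sel <- ga_select(colnames(X), X, y,
                   ga_config(population_size = 20, generations = 15,
                             rounds = 3, seed = 3))
  expect_length(sel$pool_sizes, 4)
  expect_true(all(diff(sel$pool_sizes) <= 0))  # non-increasing across rounds
  expect_setequal(sel$rounds[[3]]$members, sel$subset$members)
  expect_true(all(sel$rounds[[2]]$members %in% sel$rounds[[1]]$members))
  expect_true(all(sel$rounds[[3]]$members %in% sel$rounds[[2]]$members))
})

test_that("hill climb returns the exhaustive-search optimum unchanged", {
  toy <- toy_regression(n = 25, k = 8, noise = 0.3, seed = 13)
  pool <- colnames(toy$X)
  fits <- vapply(all_subsets(pool),
                 function(s) fitness_loo_rmse(s, toy$X, toy$y), numeric(1))
  best <- all_subsets(pool)[[which.min(fits)]]
  hc <- hill_climb_optimize(best, pool, toy$X, toy$y)
  expect_setequal(hc$subset$members, best)
  expect_equal(hc$subset$fitness_rmse, min(fits), tolerance = 1e-12)
  expect_equal(nrow(hc$trace), 1)  # only the start state
})

test_that("hill climb finds a perfect predictor column and never worsens", {
  set.seed(17)
  X <- matrix(rnorm(20 * 5), 20, 5,
              dimnames = list(NULL, paste0("V", 1:5)))
  y <- X[, 3]  # zero-noise: V3 is the response itself
  hc <- hill_climb_optimize("V1", colnames(X), X, y,
                            fitness_regressor("ridge", lambda = 1e-10))
  expect_true("V3" %in% hc$subset$members)
  expect_lt(hc$subset$fitness_rmse, 1e-4)
  start_fit <- fitness_loo_rmse("V1", X, y,
                                fitness_regressor("ridge", lambda = 1e-10))
  expect_lte(hc$subset$fitness_rmse, start_fit)
})

test_that("hill climb from every singleton reaches a verified local optimum", {
  toy <- toy_regression(n = 20, k = 6, noise = 0.3, seed = 23)
  pool <- colnames(toy$X)
  for (start in pool) {
    hc <- hill_climb_optimize(start, pool, toy$X, toy$y)
    m <- hc$subset$members
    f <- hc$subset$fitness_rmse
    # oracle: check every one-move neighbour explicitly
    neighbours <- c(
      lapply(m, function(d) setdiff(m, d)),
      lapply(setdiff(pool, m), function(d) c(m, d)))
    neighbours <- Filter(length, neighbours)
    nf <- vapply(neighbours, function(s) fitness_loo_rmse(s, toy$X, toy$y),
                 numeric(1))
    expect_true(all(nf >= f - 1e-9))
  }
})

test_that("moves that do not strictly improve the fitness are rejected", {
  # an all-zero column leaves the ridge LOO predictions unchanged (its
  # coefficient is exactly 0), so the climb must never add it
  set.seed(3)
  X <- cbind(matrix(rnorm(30), 15, 2, dimnames = list(NULL, c("A", "B"))),
             Z = 0)
  y <- X[, "A"] + rnorm(15, 0, 0.1)
  hc <- hill_climb_optimize("A", colnames(X), X, y)
  expect_false("Z" %in% hc$subset$members)
})

test_that("select_variables produces a well-formed trace and is deterministic", {
  set.seed(41)
  n <- 50
  X <- matrix(rnorm(n * 12), n, 12,
              dimnames = list(NULL, sprintf("V%02d", 1:12)))
  y <- X[, 1] - X[, 2] + rnorm(n, 0, 0.2)
  cfg <- ga_config(population_size = 16, generations = 10, rounds = 2, seed = 9)
  s1 <- select_variables(colnames(X), X, y, cfg,
                         svr_cfg = svr_config(gamma = 0.05, epsilon = 0.1,
                                              cost = 10))
  s2 <- select_variables(colnames(X), X, y, cfg,
                         svr_cfg = svr_config(gamma = 0.05, epsilon = 0.1,
                                              cost = 10))
  expect_identical(s1$subset$members, s2$subset$members)
  expect_identical(s1$trace, s2$trace)
  expect_equal(s1$trace$stage,
               c("initial", "ga_round_1", "ga_round_2", "hill_climb"))
  expect_true(all(c("rmse_10fold", "q2_10fold", "rmse_loo", "q2_loo")
                  %in% names(s1$trace)))
  expect_true(all(is.finite(s1$trace$rmse_loo)))
})

test_that("surviving pathway columns collapse into a single MPF column", {
  set.seed(8)
  X <- cbind(mol1 = rnorm(20), pwA = rbinom(20, 1, 0.4),
             pwB = rbinom(20, 1, 0.4))
  attr(X, "column_origin") <- c(mol1 = "molecular", pwA = "pathway",
                                pwB = "pathway")
  col <- collapse_pathways_to_mpf(c("mol1", "pwA", "pwB"), X)
  expect_setequal(col$members, c("mol1", "MPF"))
  expect_setequal(col$selected_pathways, c("pwA", "pwB"))
  expect_equal(unname(col$matrix[, "MPF"]),
               as.numeric(X[, "pwA"] | X[, "pwB"]))
  expect_equal(unname(attr(col$matrix, "column_origin")["MPF"]), "mpf")
  # no pathway members: unchanged
  col2 <- collapse_pathways_to_mpf("mol1", X)
  expect_identical(col2$members, "mol1")
})
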