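test_that("rmse matches hand-computed values", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 0), c(1, 1)), 1.0)
  expect_equal(rmse(c(0, 0, 0), c(1, 2, 2)), sqrt(3))  # (1+4+4)/3 = 3
  expect_error(rmse(1:3, 1:2), "equal-length")
})

test_that("q2 satisfies its sign and identity contracts", {
  y <- c(1, 2, 3, 4, 5)
  expect_equal(q2(y, y), 1.0)
  expect_equal(q2(y, rep(mean(y), 5)), 0.0)
  expect_lt(q2(y, rev(y)), 0)                       # worse than the mean
  expect_error(q2(rep(2, 4), rep(2, 4)), "constant")
  # identity: Q2 = 1 - (RMSE^2 * n) / TSS on any assembled vector
  set.seed(1)
  pred <- y + rnorm(5)
  expect_equal(q2(y, pred),
               1 - (rmse(y, pred)^2 * 5) / sum((y - mean(y))^2),
               tolerance = 1e-12)
})

test_that("svr_fit respects the epsilon tube on constant responses", {
  X <- matrix(rnorm(30), 15, 2, dimnames = list(NULL, c("a", "b")))
  y <- rep(2.5, 15)
  fit <- svr_fit(X, y, svr_config(gamma = 0.1, epsilon = 0.2, cost = 10))
  expect_true(all(abs(predict(fit, X) - 2.5) <= 0.2 + 1e-6))
  expect_error(svr_fit(X[1:2, ], y[1:2]), "at least 3")
})

test_that("svr approaches the least-squares oracle on noiseless linear data", {
  set.seed(2)
  X <- matrix(seq(-2, 2, length.out = 20), 20, 1, dimnames = list(NULL, "x"))
  y <- as.numeric(X[, 1])
  tr <- seq(1, 20, by = 2)
  gs <- grid_search(X[tr, , drop = FALSE], y[tr],
                    grid = expand.grid(gamma = c(0.1, 0.5, 1),
                                       epsilon = c(0.01, 0.05),
                                       cost = c(10, 100)),
                    scheme = "loo")
  fit <- svr_fit(X[tr, , drop = FALSE], y[tr], gs$best)
  pred <- predict(fit, X[-tr, , drop = FALSE])
  ols <- predict(lm(yy ~ xx, data.frame(yy = y[tr], xx = X[tr, 1])),
                 data.frame(xx = X[-tr, 1]))
  expect_lt(rmse(y[-tr], pred), sd(y) / 10)
  expect_lt(rmse(y[-tr], pred), rmse(y[-tr], ols) + 0.05)
})

test_that("an epsilon tube wider than the response span yields a flat model", {
  set.seed(4)
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  y <- rnorm(20)
  eps <- max(abs(y - mean(y))) * 1.5
  fit <- svr_fit(X, y, svr_config(gamma = 0.1, epsilon = eps, cost = 10))
  pred <- predict(fit, X)
  expect_lt(diff(range(pred)), 1e-6)
})

test_that("cross_validate LOO matches an explicit n-refit loop", {
  toy <- toy_regression(n = 15, k = 3, noise = 0.2)
  cfg <- svr_config(gamma = 0.1, epsilon = 0.1, cost = 10)
  cv <- cross_validate(toy$X, toy$y, cfg, scheme = "loo")
  expect_equal(cv$n_refits, 15)
  oracle <- bf_loo_pred(toy$X, toy$y,
                        function(X, y) svr_fit(X, y, cfg),
                        function(m, x) predict(m, x))
  expect_equal(cv$pred, oracle, tolerance = 1e-10)
  expect_equal(cv$rmse, rmse(toy$y, oracle), tolerance = 1e-10)
  expect_equal(cv$q2, q2(toy$y, oracle), tolerance = 1e-10)
})

test_that("10-fold assignment is seeded and balanced", {
  toy <- toy_regression(n = 25, k = 3)
  cfg <- svr_config(gamma = 0.1, epsilon = 0.1, cost = 10)
  cv1 <- cross_validate(toy$X, toy$y, cfg, scheme = "kfold", folds = 10,
                        seed = 5)
  cv2 <- cross_validate(toy$X, toy$y, cfg, scheme = "kfold", folds = 10,
                        seed = 5)
  expect_identical(cv1$pred, cv2$pred)
  expect_equal(cv1$n_refits, 10)
  expect_error(cross_validate(toy$X[1:5, ], toy$y[1:5], cfg,
                              scheme = "kfold", folds = 10), "folds")
})

test_that("grid_search returns the exhaustive minimum with deterministic ties", {
  set.seed(6)
  X <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("a", "b")))
  y <- sin(X[, 1]) + rnorm(30, 0, 0.1)
  grid <- expand.grid(gamma = c(0.01, 0.1, 1), epsilon = c(0.1, 0.3),
                      cost = c(1, 10))
  gs <- grid_search(X, y, grid, scheme = "kfold", folds = 5, seed = 2)
  expect_equal(min(gs$table$cv_rmse),
               gs$table$cv_rmse[gs$table$gamma == gs$best$gamma &
                                gs$table$epsilon == gs$best$epsilon &
                                gs$table$cost == gs$best$cost])
  # singleton grid
  single <- grid_search(X, y, data.frame(gamma = 0.1, epsilon = 0.2, cost = 5))
  expect_equal(single$best$cost, 5)
  # duplicated grid point: deterministic result
  dup <- rbind(grid[1, ], grid[1, ])
  gs2 <- grid_search(X, y, dup, scheme = "kfold", folds = 5, seed = 2)
  expect_equal(unclass(gs2$best)[c("gamma", "epsilon", "cost")],
               list(gamma = grid$gamma[1], epsilon = grid$epsilon[1],
                    cost = grid$cost[1]))
  expect_error(grid_search(X, y, grid[0, ]), "empty")
})

test_that("validation_report carries consistent internal and external metrics", {
  toy <- toy_regression(n = 40, k = 3, noise = 0.2, seed = 77)
  tr <- 1:28
  vr <- validation_report(toy$X[tr, ], toy$y[tr], toy$X[-tr, ], toy$y[-tr],
                          cfg = svr_config(gamma = 0.1, epsilon = 0.1,
                                           cost = 10), seed = 3)
  expect_equal(vr$n_train, 28)
  expect_equal(vr$m, 3)
  expect_true(vr$r2_train >= 0 && vr$r2_train <= 1)
  expect_true(vr$q2_loo <= 1 && vr$q2_10fold <= 1)
  expect_gte(vr$rmse_test, 0)
  expect_true(is.finite(vr$error_variance_loo) &&
              is.finite(vr$error_variance_test))
  # train-mean convention changes only the denominator of the external Q2
  vr2 <- validation_report(toy$X[tr, ], toy$y[tr], toy$X[-tr, ], toy$y[-tr],
                           cfg = svr_config(gamma = 0.1, epsilon = 0.1,
                                            cost = 10), seed = 3,
                           q2_test_reference = "train")
  expect_equal(vr2$rmse_test, vr$rmse_test)
  expect_false(isTRUE(all.equal(vr2$q2_test, vr$q2_test)))
})

test_that("kernlab agreement: our predictions match an independent SVR engine", {
  skip_if_not_installed("e1071")
  toy <- toy_regression(n = 30, k = 3, noise = 0.2, seed = 11)
  cfg <- svr_config(gamma = 0.1, epsilon = 0.1, cost = 10)
  fit <- svr_fit(toy$X, toy$y, cfg)
  alt <- e1071::svm(toy$X, toy$y, type = "eps-regression", kernel = "radial",
                    gamma = cfg$gamma, epsilon = cfg$epsilon, cost = cfg$cost,
                    scale = FALSE)
  expect_equal(predict(fit, toy$X), unname(predict(alt, toy$X)),
               tolerance = 0.02)
})

test_that("SVR models persist to JSON and predict identically after reload", {
  toy <- toy_regression(n = 20, k = 3, noise = 0.2, seed = 19)
  fit <- svr_fit(toy$X, toy$y, svr_config(gamma = 0.2, epsilon = 0.1,
                                          cost = 5))
  path <- withr::local_tempfile(fileext = ".json")
  save_svr(fit, path)
  back <- load_svr(path)
  expect_equal(predict(back, toy$X), predict(fit, toy$X), tolerance = 1e-8)
})

test_that("repeated trials summarize split-to-split variability", {
  # noiseless smooth response on a dense bounded design: split-to-split
  # variability of the test error is small compared to the response spread
  set.seed(55)
  X <- matrix(runif(60, -2, 2), 60, 1, dimnames = list(NULL, "x"))
  y <- sin(X[, 1])
  rt <- repeated_trials(X, y, n_train = 45,
                        cfg = svr_config(gamma = 1, epsilon = 0.01,
                                         cost = 100),
                        n_trials = 4, seed = 2, folds = 5)
  expect_equal(rt$n_trials, 4)
  expect_equal(nrow(rt$trials), 4)
  expect_lt(rt$summary$sd[rt$summary$metric == "rmse_test"], sd(y) / 10)
  expect_lt(rt$summary$mean[rt$summary$metric == "rmse_test"], sd(y) / 5)
  expect_error(repeated_trials(X, y, 45, n_trials = 1), ">= 2")
})
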