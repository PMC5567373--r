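#' Root-mean-square error
#'
#' \eqn{RMSE = \sqrt{\frac{1}{n}\sum (Y_{exp} - Y_{pred})^2}}.
#'
#' @param y_exp,y_pred Numeric vectors of equal length (>= 1).
#' @return Non-negative real.
#' @export
rmse <- function(y_exp, y_pred) {
  if (length(y_exp) != length(y_pred) || length(y_exp) < 1L)
    stop("`y_exp` and `y_pred` must be equal-length, non-empty", call. = FALSE)
  sqrt(mean((y_exp - y_pred)^2))
}

#' Cross-validated correlation coefficient Q-squared
#'
#' \eqn{Q^2 = 1 - \sum (Y_{exp} - Y_{pred})^2 / \sum (Y_{exp} - Y_{mean})^2},
#' with \eqn{Y_{mean}} the mean of the evaluated observations. Can be
#' negative when predictions are worse than the mean.
#'
#' @inheritParams rmse
#' @param y_mean Reference mean for the denominator; defaults to
#'   `mean(y_exp)` (use the training mean to get the alternative external-
#'   validation convention).
#' @return Real number <= 1.
#' @export
q2 <- function(y_exp, y_pred, y_mean = mean(y_exp)) {
  if (length(y_exp) != length(y_pred) || length(y_exp) < 2L)
    stop("`y_exp` and `y_pred` must be equal-length with n >= 2", call. = FALSE)
  tss <- sum((y_exp - y_mean)^2)
  if (tss == 0)
    stop("`y_exp` is constant; Q-squared undefined (zero denominator)",
         call. = FALSE)
  1 - sum((y_exp - y_pred)^2) / tss
}

#' Squared Pearson correlation between observed and predicted values
#'
#' The conventional QSAR R-squared of a fitted or predicted set.
#'
#' @inheritParams rmse
#' @return Real in \[0, 1\].
#' @export
r_squared <- function(y_exp, y_pred) {
  if (stats::sd(y_exp) == 0 || stats::sd(y_pred) == 0) return(0)
  stats::cor(y_exp, y_pred)^2
}

#' epsilon-SVR configuration
#'
#' Parameters of the Gaussian radial-basis-function support-vector regressor
#' \eqn{\exp\{-\gamma |\mu - \nu|^2\}}: kernel width `gamma`, insensitivity
#' tube half-width `epsilon` (in -logC units) and box constraint `cost`.
#'
#' @param gamma RBF width, > 0.
#' @param epsilon Tube half-width, >= 0.
#' @param cost Box constraint C, > 0.
#' @return A list of class `svr_config`.
#' @export
svr_config <- function(gamma = 0.01, epsilon = 0.20, cost = 11) {
  stopifnot_scalar_number(gamma, "gamma", positive = TRUE)
  stopifnot_scalar_number(epsilon, "epsilon")
  if (epsilon < 0) stop("`epsilon` must be >= 0", call. = FALSE)
  stopifnot_scalar_number(cost, "cost", positive = TRUE)
  structure(list(gamma = gamma, epsilon = epsilon, cost = cost),
            class = "svr_config")
}

#' Fit an epsilon-SVR with RBF kernel
#'
#' Thin wrapper around [kernlab::ksvm()] (`type = "eps-svr"`). Features are
#' used as-is (no internal scaling) unless `scale = TRUE`.
#'
#' @param X Numeric training matrix (rows = samples, columns = the selected
#'   descriptors; at least 3 rows).
#' @param y Numeric response (-logC), length `nrow(X)`.
#' @param cfg An [svr_config()].
#' @param scale Standardize columns before fitting (default `FALSE`; when
#'   enabled, the scaling is stored and applied at prediction).
#' @return Object of class `metaconc_svr` supporting `predict()`.
#' @export
svr_fit <- function(X, y, cfg = svr_config(), scale = FALSE) {
  X <- as.matrix(X)
  if (nrow(X) < 3L) stop("need at least 3 training rows", call. = FALSE)
  if (length(y) != nrow(X)) stop("`y` length must match rows of `X`", call. = FALSE)
  if (ncol(X) < 1L) stop("empty descriptor subset", call. = FALSE)
  ctr <- NULL; scl <- NULL
  if (scale) {
    ctr <- colMeans(X)
    scl <- apply(X, 2L, stats::sd)
    scl[scl == 0] <- 1
    X <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  }
  model <- tryCatch(
    kernlab::ksvm(X, y, type = "eps-svr", kernel = "rbfdot",
                  kpar = list(sigma = cfg$gamma), C = cfg$cost,
                  epsilon = cfg$epsilon, scaled = FALSE),
    error = function(e) {
      # every residual inside the epsilon tube: the SVR optimum is the flat
      # model with no support vectors; represent it explicitly
      if (grepl("No Support Vectors", conditionMessage(e), fixed = TRUE))
        return(NULL)
      stop(sprintf("SVR fit failed (degenerate kernel matrix?): %s",
                   conditionMessage(e)), call. = FALSE)
    })
  structure(list(model = model, cfg = cfg, features = colnames(X),
                 center = ctr, scale = scl,
                 constant = if (is.null(model)) mean(y)),
            class = "metaconc_svr")
}

#' @export
predict.metaconc_svr <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(object$features) && !is.null(colnames(X)))
    X <- X[, object$features, drop = FALSE]
  if (!is.null(object$center))
    X <- sweep(sweep(X, 2L, object$center), 2L, object$scale, "/")
  if (is.null(object$model)) return(rep(object$constant, nrow(X)))
  as.numeric(kernlab::predict(object$model, X))
}

#' Persist / restore a fitted SVR as portable JSON
#'
#' Stores the configuration, feature names, support vectors, their
#' coefficients and the intercept, so a model can be re-used without binary
#' serialization.
#'
#' @param fit A `metaconc_svr`.
#' @param path JSON path.
#' @return `save_svr` returns `path` invisibly; `load_svr` returns an object
#'   of class `metaconc_svr_json` supporting `predict()`.
#' @export
save_svr <- function(fit, path) {
  m <- fit$model
  if (is.null(m)) {
    sv <- matrix(numeric(0), 0, length(fit$features))
    cf <- numeric(0)
    icpt <- -fit$constant
  } else {
    sv <- kernlab::xmatrix(m)
    if (is.list(sv)) sv <- sv[[1]]
    cf <- kernlab::coef(m)
    if (is.list(cf)) cf <- cf[[1]]
    icpt <- as.numeric(kernlab::b(m))
  }
  obj <- list(format = "metaconc_svr", version = 1L,
              cfg = unclass(fit$cfg), features = fit$features,
              center = fit$center, scale = fit$scale,
              support_vectors = unname(as.matrix(sv)),
              coefficients = as.numeric(cf),
              intercept = icpt)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_svr
#' @export
load_svr <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "metaconc_svr"))
    stop("not a metaconc SVR model file", call. = FALSE)
  obj$support_vectors <- as.matrix(obj$support_vectors)
  structure(obj, class = "metaconc_svr_json")
}

#' @export
predict.metaconc_svr_json <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(object$features) && !is.null(colnames(X)))
    X <- X[, object$features, drop = FALSE]
  if (!is.null(object$center) && length(object$center))
    X <- sweep(sweep(X, 2L, object$center), 2L, object$scale, "/")
  if (length(object$coefficients) == 0L)
    return(rep(-object$intercept, nrow(X)))
  sv <- object$support_vectors
  d2 <- outer(rowSums(X^2), rowSums(sv^2), "+") - 2 * X %*% t(sv)
  K <- exp(-object$cfg$gamma * pmax(d2, 0))
  as.numeric(K %*% object$coefficients - object$intercept)
}

make_folds <- function(n, k, seed) {
  if (k > n) stop("more folds than samples", call. = FALSE)
  perm <- with_seed(seed, sample.int(n))
  fold <- rep(seq_len(k), length.out = n)[order(perm)]
  fold
}

#' Cross-validate an epsilon-SVR
#'
#' Leave-one-out or seeded 10-fold cross-validation; out-of-fold predictions
#' are assembled over all rows and the RMSE / Q-squared computed once on the
#' assembled vector.
#'
#' @inheritParams svr_fit
#' @param scheme `"loo"` or `"kfold"`.
#' @param folds Number of folds for `"kfold"` (default 10).
#' @param seed Seed for the fold assignment (ignored for LOO).
#' @return List with `pred` (assembled out-of-fold predictions), `rmse`, `q2`,
#'   `scheme`, `n_refits`.
#' @export
cross_validate <- function(X, y, cfg = svr_config(),
                           scheme = c("loo", "kfold"), folds = 10L,
                           seed = 1L, scale = FALSE) {
  scheme <- match.arg(scheme)
  X <- as.matrix(X)
  n <- nrow(X)
  fold <- if (scheme == "loo") seq_len(n) else make_folds(n, folds, seed)
  pred <- rep(NA_real_, n)
  for (f in unique(fold)) {
    te <- fold == f
    fit <- svr_fit(X[!te, , drop = FALSE], y[!te], cfg, scale = scale)
    pred[te] <- predict(fit, X[te, , drop = FALSE])
  }
  list(pred = pred, rmse = rmse(y, pred), q2 = q2(y, pred),
       scheme = scheme, n_refits = length(unique(fold)))
}

#' Default hyperparameter grid
#'
#' Candidate values bracketing the tuned optimum reported for this class of
#' model (gamma 0.01, epsilon 0.20, cost 11).
#'
#' @return data.frame of gamma/epsilon/cost combinations.
#' @export
default_svr_grid <- function() {
  expand.grid(gamma = c(0.001, 0.01, 0.1, 1),
              epsilon = c(0.05, 0.1, 0.2, 0.4),
              cost = c(1, 11, 100))
}

#' Grid-search SVR hyperparameters by cross-validated RMSE
#'
#' Evaluates every grid point and returns the one minimizing the CV RMSE;
#' ties are broken toward smaller cost, then smaller gamma, then smaller
#' epsilon.
#'
#' @inheritParams cross_validate
#' @param grid data.frame with columns gamma, epsilon, cost.
#' @return List: `best` (an [svr_config()]), `table` (the grid with an added
#'   `cv_rmse` column).
#' @export
grid_search <- function(X, y, grid = default_svr_grid(),
                        scheme = c("loo", "kfold"), folds = 10L, seed = 1L,
                        scale = FALSE) {
  scheme <- match.arg(scheme)
  if (nrow(grid) == 0L) stop("empty grid", call. = FALSE)
  cv_rmse <- vapply(seq_len(nrow(grid)), function(i) {
    cfg <- svr_config(grid$gamma[i], grid$epsilon[i], grid$cost[i])
    cross_validate(X, y, cfg, scheme = scheme, folds = folds, seed = seed,
                   scale = scale)$rmse
  }, numeric(1))
  ord <- order(cv_rmse, grid$cost, grid$gamma, grid$epsilon)
  best <- ord[1L]
  list(best = svr_config(grid$gamma[best], grid$epsilon[best], grid$cost[best]),
       table = cbind(grid, cv_rmse = cv_rmse))
}

#' Full validation report for a selected variable set
#'
#' Fits on the training rows and reports the training R-squared, 10-fold and
#' LOO RMSE / Q-squared, and — when test rows are given — external R-squared,
#' RMSE, Q-squared, plus the variance of the LOO and test prediction errors.
#'
#' @param X_train,y_train Training matrix (selected descriptors) and response.
#' @param X_test,y_test Optional held-out set.
#' @inheritParams cross_validate
#' @param q2_test_reference `"test"` (default: test-set mean in the Q-squared
#'   denominator) or `"train"`.
#' @return List of class `validation_report`.
#' @export
validation_report <- function(X_train, y_train, X_test = NULL, y_test = NULL,
                              cfg = svr_config(), folds = 10L, seed = 1L,
                              scale = FALSE,
                              q2_test_reference = c("test", "train")) {
  q2_test_reference <- match.arg(q2_test_reference)
  fit <- svr_fit(X_train, y_train, cfg, scale = scale)
  cv10 <- cross_validate(X_train, y_train, cfg, scheme = "kfold",
                         folds = folds, seed = seed, scale = scale)
  loo <- cross_validate(X_train, y_train, cfg, scheme = "loo", scale = scale)
  rep <- list(n_train = nrow(as.matrix(X_train)),
              m = ncol(as.matrix(X_train)),
              r2_train = r_squared(y_train, predict(fit, X_train)),
              rmse_10fold = cv10$rmse, q2_10fold = cv10$q2,
              rmse_loo = loo$rmse, q2_loo = loo$q2,
              error_variance_loo = stats::var(y_train - loo$pred),
              cfg = cfg)
  if (!is.null(X_test)) {
    pred <- predict(fit, X_test)
    ref <- if (q2_test_reference == "test") mean(y_test) else mean(y_train)
    rep$n_test <- nrow(as.matrix(X_test))
    rep$r2_test <- r_squared(y_test, pred)
    rep$rmse_test <- rmse(y_test, pred)
    rep$q2_test <- q2(y_test, pred, y_mean = ref)
    rep$error_variance_test <- stats::var(y_test - pred)
  }
  rep$fit <- fit
  class(rep) <- "validation_report"
  rep
}

#' Repeated random-split trials
#'
#' Re-splits the data `n_trials` times, refits and validates, and reports the
#' mean and standard deviation of every metric (the confidence-interval
#' convention of repeated randomized trials).
#'
#' @param X Full feature matrix restricted to the selected descriptors.
#' @param y Response vector.
#' @param n_train Training-set size per trial.
#' @param cfg An [svr_config()].
#' @param n_trials Number of trials (>= 2, default 20).
#' @param seed Master seed; per-trial split seeds are drawn from it.
#' @inheritParams validation_report
#' @return List: `summary` (data.frame metric/mean/sd) and `trials`
#'   (data.frame of per-trial metrics).
#' @export
repeated_trials <- function(X, y, n_train, cfg = svr_config(),
                            n_trials = 20L, seed = 1L, folds = 10L,
                            scale = FALSE) {
  if (n_trials < 2L) stop("`n_trials` must be >= 2", call. = FALSE)
  X <- as.matrix(X)
  n <- nrow(X)
  trial_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_trials))
  rows <- lapply(seq_len(n_trials), function(t) {
    idx <- with_seed(trial_seeds[t], sample.int(n, n_train))
    vr <- validation_report(X[idx, , drop = FALSE], y[idx],
                            X[-idx, , drop = FALSE], y[-idx],
                            cfg = cfg, folds = folds, seed = trial_seeds[t],
                            scale = scale)
    data.frame(trial = t, r2_train = vr$r2_train,
               rmse_10fold = vr$rmse_10fold, q2_10fold = vr$q2_10fold,
               rmse_loo = vr$rmse_loo, q2_loo = vr$q2_loo,
               r2_test = vr$r2_test, rmse_test = vr$rmse_test,
               q2_test = vr$q2_test)
  })
  trials <- do.call(rbind, rows)
  metrics <- setdiff(names(trials), "trial")
  summary <- data.frame(metric = metrics,
                        mean = vapply(metrics, function(m) mean(trials[[m]]), numeric(1)),
                        sd = vapply(metrics, function(m) stats::sd(trials[[m]]), numeric(1)),
                        row.names = NULL)
  list(summary = summary, trials = trials, n_trials = n_trials)
}
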