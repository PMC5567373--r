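#' Fitness regressor configuration
#'
#' The selection fitness is the leave-one-out RMSE of a regressor restricted
#' to the candidate descriptor subset. Two engines are available:
#' `"ridge"` — linear ridge regression with the exact closed-form LOO
#' residuals \eqn{e_i / (1 - h_{ii})}, fast enough to sit inside a GA loop —
#' and `"svr"`, the same epsilon-SVR used for the final model, evaluated by an
#' explicit n-refit LOO loop.
#'
#' @param type `"ridge"` or `"svr"`.
#' @param lambda Ridge penalty (not applied to the intercept).
#' @param svr An [svr_config()] used when `type = "svr"`.
#' @return A list of class `fitness_regressor`.
#' @export
fitness_regressor <- function(type = c("ridge", "svr"), lambda = 1e-6,
                              svr = svr_config()) {
  type <- match.arg(type)
  structure(list(type = type, lambda = lambda, svr = svr),
            class = "fitness_regressor")
}

# Closed-form LOO predictions for ridge regression with intercept.
# X: n x k (k may be 0 -> intercept-only). Returns the LOO prediction vector.
ridge_loo_pred <- function(X, y, lambda) {
  n <- length(y)
  X1 <- cbind(`(Intercept)` = 1, X)
  k <- ncol(X1)
  pen <- diag(c(0, rep(lambda, k - 1L)), k)
  A <- crossprod(X1) + pen
  Ainv <- tryCatch(solve(A), error = function(e) NULL)
  if (is.null(Ainv)) {
    Ainv <- solve(A + diag(1e-8, k))
  }
  H <- X1 %*% Ainv %*% t(X1)
  h <- diag(H)
  yhat <- as.numeric(H %*% y)
  denom <- 1 - h
  denom[denom < 1e-12] <- 1e-12
  (yhat - h * y) / denom
}

#' Leave-one-out RMSE fitness of a descriptor subset
#'
#' Computes LOO predictions with the configured regressor restricted to the
#' subset columns and applies the RMSE formula once to the assembled
#' prediction vector. This is the optimization objective of both the genetic
#' algorithm and the add/remove hill climb.
#'
#' @param subset Character vector of descriptor names (non-empty).
#' @param X Feature matrix (all candidate columns).
#' @param y Response (-logC), length `nrow(X)` >= 3.
#' @param regressor A [fitness_regressor()].
#' @return Non-negative LOO RMSE.
#' @export
fitness_loo_rmse <- function(subset, X, y, regressor = fitness_regressor()) {
  if (length(subset) == 0L) stop("empty subset has no fitness", call. = FALSE)
  if (length(y) < 3L) stop("need at least 3 samples", call. = FALSE)
  X <- as.matrix(X)
  miss <- setdiff(subset, colnames(X))
  if (length(miss))
    stop(sprintf("unknown descriptors: %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  Xs <- X[, subset, drop = FALSE]
  if (regressor$type == "ridge") {
    # guard: more columns than LOO training rows makes the fit ill-posed
    if (ncol(Xs) >= length(y) - 1L) return(Inf)
    pred <- ridge_loo_pred(Xs, y, regressor$lambda)
  } else {
    n <- length(y)
    pred <- vapply(seq_len(n), function(i) {
      fit <- svr_fit(Xs[-i, , drop = FALSE], y[-i], regressor$svr)
      predict(fit, Xs[i, , drop = FALSE])
    }, numeric(1))
  }
  rmse(y, pred)
}

#' Genetic-algorithm configuration
#'
#' Defaults follow the published selection protocol: population 100, 100
#' generations, bit-flip mutation rate 0.01, three chained rounds. The
#' operators are standard generational-GA equivalents: tournament selection of
#' size 2, uniform crossover (rate 0.8), single-elite carryover. `init_p` sets
#' the Bernoulli inclusion probability of each descriptor in the initial
#' population (expected subset size ~ 40% of the pool).
#'
#' @param population_size Number of chromosomes per generation (at least 2).
#' @param generations Number of generations.
#' @param mutation_rate Per-bit flip probability in \[0, 1\].
#' @param rounds Chained GA rounds (each round's pool is the previous round's
#'   selected subset).
#' @param crossover_rate Probability a selected pair undergoes uniform
#'   crossover.
#' @param init_p Initial per-bit inclusion probability.
#' @param seed Integer seed making the whole selection reproducible.
#' @param regressor A [fitness_regressor()].
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(population_size = 100L, generations = 100L,
                      mutation_rate = 0.01, rounds = 3L,
                      crossover_rate = 0.8, init_p = 0.4, seed = 1L,
                      regressor = fitness_regressor()) {
  if (population_size < 2L) stop("`population_size` must be >= 2", call. = FALSE)
  if (mutation_rate < 0 || mutation_rate > 1)
    stop("`mutation_rate` must be in [0, 1]", call. = FALSE)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 mutation_rate = mutation_rate, rounds = as.integer(rounds),
                 crossover_rate = crossover_rate, init_p = init_p,
                 seed = as.integer(seed), regressor = regressor),
            class = "ga_config")
}

new_subset <- function(members, fitness) {
  structure(list(members = sort(members), fitness_rmse = fitness),
            class = "variable_subset")
}

# Fitness with memoisation keyed on the sorted member string.
make_fitness_cache <- function(X, y, regressor) {
  cache <- new.env(parent = emptyenv())
  function(members) {
    if (length(members) == 0L) return(Inf)
    key <- paste(sort(members), collapse = "\r")
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- fitness_loo_rmse(members, X, y, regressor)
    cache[[key]] <- val
    val
  }
}

#' One genetic-algorithm selection round
#'
#' Evolves bit-vector chromosomes over the candidate pool; the fitness of a
#' chromosome is the LOO RMSE of its descriptor subset (lower is better).
#' With single-elite carryover the best-so-far fitness is non-increasing over
#' generations. Returns the best subset found.
#'
#' @param pool Character vector of candidate descriptor names (>= 2).
#' @param X Feature matrix containing at least the pool columns.
#' @param y Response vector.
#' @param cfg A [ga_config()]; `cfg$seed` controls all randomness.
#' @param init_population Optional 0/1 matrix (rows = chromosomes, columns =
#'   pool) overriding the random initial population.
#' @return A list of class `variable_subset`: `members`, `fitness_rmse`, plus
#'   `history` (best fitness per generation).
#' @export
ga_round <- function(pool, X, y, cfg = ga_config(), init_population = NULL) {
  if (length(pool) < 2L) stop("pool must hold at least 2 descriptors", call. = FALSE)
  X <- as.matrix(X)
  fit_fun <- make_fitness_cache(X, y, cfg$regressor)
  p <- length(pool)
  ps <- cfg$population_size
  res <- with_seed(cfg$seed, {
    pop <- if (!is.null(init_population)) {
      m <- as.matrix(init_population)
      m[rep(seq_len(nrow(m)), length.out = ps), , drop = FALSE]
    } else {
      m <- matrix(stats::rbinom(ps * p, 1L, cfg$init_p), ps, p)
      # empty chromosomes are revived with one random bit
      for (i in which(rowSums(m) == 0L)) m[i, sample.int(p, 1L)] <- 1L
      m
    }
    colnames(pop) <- pool
    fitv <- apply(pop, 1L, function(bits) fit_fun(pool[bits == 1L]))
    best_hist <- numeric(cfg$generations)
    for (gen in seq_len(cfg$generations)) {
      elite <- which.min(fitv)
      nextpop <- matrix(0L, ps, p)
      nextpop[1L, ] <- pop[elite, ]
      for (i in seq(2L, ps)) {
        # tournament selection, size 2
        pick <- function() {
          c2 <- sample.int(ps, 2L)
          c2[which.min(fitv[c2])]
        }
        pa <- pop[pick(), ]
        pb <- pop[pick(), ]
        child <- if (stats::runif(1) < cfg$crossover_rate) {
          mask <- stats::rbinom(p, 1L, 0.5) == 1L
          ifelse(mask, pa, pb)
        } else pa
        flip <- stats::runif(p) < cfg$mutation_rate
        child[flip] <- 1L - child[flip]
        nextpop[i, ] <- child
      }
      pop <- nextpop
      colnames(pop) <- pool
      fitv <- apply(pop, 1L, function(bits) fit_fun(pool[bits == 1L]))
      best_hist[gen] <- min(fitv)
    }
    best <- which.min(fitv)
    list(members = pool[pop[best, ] == 1L], fitness = fitv[best],
         history = cummin(best_hist))
  })
  out <- new_subset(res$members, res$fitness)
  out$history <- res$history
  out
}

#' Chained multi-round GA selection
#'
#' Runs `cfg$rounds` GA rounds; each round's candidate pool is the subset
#' selected by the previous round. The per-round pool size therefore shrinks
#' as fitness dictates (no forced quota).
#'
#' @inheritParams ga_round
#' @return List: `subset` (final `variable_subset`), `rounds` (list of
#'   per-round subsets), `pool_sizes` (integer vector, initial pool first).
#' @export
ga_select <- function(pool, X, y, cfg = ga_config()) {
  if (length(pool) < 2L)
    stop("pool must hold at least 2 descriptors", call. = FALSE)
  rounds <- vector("list", cfg$rounds)
  sizes <- integer(cfg$rounds + 1L)
  sizes[1L] <- length(pool)
  current <- pool
  round_seeds <- with_seed(cfg$seed, sample.int(.Machine$integer.max - 1L,
                                                cfg$rounds))
  for (r in seq_len(cfg$rounds)) {
    if (length(current) < 2L) {
      rounds[r] <- rounds[r - 1L]
      sizes[r + 1L] <- length(current)
      next
    }
    rcfg <- cfg
    rcfg$seed <- round_seeds[r]
    rounds[[r]] <- ga_round(current, X, y, rcfg)
    current <- rounds[[r]]$members
    sizes[r + 1L] <- length(current)
  }
  list(subset = rounds[[cfg$rounds]], rounds = rounds, pool_sizes = sizes)
}

#' Steepest-descent add/remove optimization
#'
#' From the current subset, each iteration evaluates every single-descriptor
#' deletion and every single-descriptor addition from the full preprocessed
#' pool, and accepts the move with the lowest LOO RMSE provided it strictly
#' improves on the current value; it stops at a local minimum. Ties on equal
#' RMSE prefer the smaller subset, then the lexicographically earlier
#' changed descriptor. The result is never worse than the input.
#'
#' @param current A `variable_subset` or character vector of member names.
#' @param full_pool All preprocessed descriptor names (superset of `current`).
#' @param X,y Feature matrix and response.
#' @param regressor A [fitness_regressor()].
#' @return List: `subset` (the optimized `variable_subset`) and `trace`
#'   (data.frame step, move, descriptor, m, rmse_loo of each accepted state).
#' @export
hill_climb_optimize <- function(current, full_pool, X, y,
                                regressor = fitness_regressor()) {
  members <- if (inherits(current, "variable_subset")) current$members
             else as.character(current)
  if (length(members) == 0L) stop("`current` must be non-empty", call. = FALSE)
  if (!all(members %in% full_pool))
    stop("`full_pool` must contain every current member", call. = FALSE)
  X <- as.matrix(X)
  fit_fun <- make_fitness_cache(X, y, regressor)
  cur_fit <- fit_fun(members)
  trace <- data.frame(step = 0L, move = "start", descriptor = NA_character_,
                      m = length(members), rmse_loo = cur_fit,
                      stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    cand <- data.frame(move = character(0), descriptor = character(0),
                       rmse = numeric(0), m = integer(0),
                       stringsAsFactors = FALSE)
    if (length(members) > 1L) {
      for (d in members)
        cand <- rbind(cand, data.frame(move = "remove", descriptor = d,
                                       rmse = fit_fun(setdiff(members, d)),
                                       m = length(members) - 1L))
    }
    for (d in setdiff(full_pool, members))
      cand <- rbind(cand, data.frame(move = "add", descriptor = d,
                                     rmse = fit_fun(c(members, d)),
                                     m = length(members) + 1L))
    if (nrow(cand) == 0L) break
    ord <- order(cand$rmse, cand$m, cand$descriptor)
    best <- cand[ord[1L], ]
    if (!(best$rmse < cur_fit)) break
    members <- if (best$move == "remove") setdiff(members, best$descriptor)
               else c(members, best$descriptor)
    cur_fit <- best$rmse
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step, move = best$move,
                                     descriptor = best$descriptor,
                                     m = length(members), rmse_loo = cur_fit))
  }
  list(subset = new_subset(members, cur_fit), trace = trace)
}

#' Full variable-selection pipeline with a per-stage evaluation trace
#'
#' Chains the GA rounds and the add/remove hill climb, evaluating each stage's
#' subset by seeded 10-fold and LOO cross-validation with the final-model
#' epsilon-SVR, and returns a selection trace in the conventional reporting
#' layout (round, m, 10-fold RMSE/Q2, LOO RMSE/Q2).
#'
#' @inheritParams ga_round
#' @param svr_cfg The [svr_config()] used for trace evaluation (and as the
#'   fitness engine when `cfg$regressor$type == "svr"`).
#' @param folds,cv_seed 10-fold settings for the trace evaluation.
#' @param evaluate_trace Set `FALSE` to skip the per-stage SVR
#'   cross-validations (the trace then carries only m and the fitness RMSE).
#' @return List: `subset`, `trace` (data.frame round, m, rmse_10fold,
#'   q2_10fold, rmse_loo, q2_loo), `ga` (the [ga_select()] result),
#'   `hill_climb` (the [hill_climb_optimize()] result).
#' @export
select_variables <- function(pool, X, y, cfg = ga_config(),
                             svr_cfg = svr_config(), folds = 10L,
                             cv_seed = 1L, evaluate_trace = TRUE) {
  eval_stage <- function(members) {
    if (!evaluate_trace)
      return(c(rmse_10fold = NA_real_, q2_10fold = NA_real_,
               rmse_loo = NA_real_, q2_loo = NA_real_))
    Xs <- X[, members, drop = FALSE]
    cv10 <- cross_validate(Xs, y, svr_cfg, scheme = "kfold", folds = folds,
                           seed = cv_seed)
    loo <- cross_validate(Xs, y, svr_cfg, scheme = "loo")
    c(rmse_10fold = cv10$rmse, q2_10fold = cv10$q2,
      rmse_loo = loo$rmse, q2_loo = loo$q2)
  }
  ga <- ga_select(pool, X, y, cfg)
  hc <- hill_climb_optimize(ga$subset, pool, X, y, cfg$regressor)
  stages <- c(list(initial = pool),
              stats::setNames(lapply(ga$rounds, `[[`, "members"),
                              paste0("ga_round_", seq_along(ga$rounds))),
              list(hill_climb = hc$subset$members))
  trace <- do.call(rbind, lapply(seq_along(stages), function(i) {
    ev <- eval_stage(stages[[i]])
    data.frame(round = i - 1L, stage = names(stages)[i],
               m = length(stages[[i]]),
               rmse_10fold = ev[["rmse_10fold"]], q2_10fold = ev[["q2_10fold"]],
               rmse_loo = ev[["rmse_loo"]], q2_loo = ev[["q2_loo"]],
               stringsAsFactors = FALSE)
  }))
  list(subset = hc$subset, trace = trace, ga = ga, hill_climb = hc)
}

#' Collapse surviving pathway variables into the MPF descriptor
#'
#' After selection, all retained binary pathway columns are replaced by one
#' Metabolite Pathways' Feature column (their element-wise OR); molecular and
#' topology members are kept unchanged. Returns the modified matrix and
#' member list; if no pathway column survived, both are returned untouched.
#'
#' @param subset Character vector of selected descriptor names.
#' @param X Feature matrix with a `column_origin` attribute.
#' @param mpf_name Name of the new column (default "MPF").
#' @return List: `members` (updated names), `matrix` (X with the MPF column
#'   appended when created), `selected_pathways` (the collapsed columns).
#' @export
collapse_pathways_to_mpf <- function(subset, X, mpf_name = "MPF") {
  X <- ensure_origin(X)
  origin <- attr(X, "column_origin")
  pw <- subset[origin[subset] == "pathway"]
  if (length(pw) == 0L)
    return(list(members = subset, matrix = X, selected_pathways = character(0)))
  mpf <- as.numeric(rowSums(X[, pw, drop = FALSE]) > 0)
  X2 <- cbind(X, mpf)
  colnames(X2)[ncol(X2)] <- mpf_name
  attr(X2, "column_origin") <- c(origin, stats::setNames("mpf", mpf_name))
  list(members = c(setdiff(subset, pw), mpf_name), matrix = X2,
       selected_pathways = pw)
}

#' Write a selection trace / selected subset
#'
#' @param trace The trace data.frame from [select_variables()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_selection_trace <- function(trace, path) {
  write_tsv_det(trace, path)
  invisible(path)
}

#' @rdname write_selection_trace
#' @param subset A `variable_subset` or character vector.
#' @export
write_subset <- function(subset, path) {
  members <- if (inherits(subset, "variable_subset")) subset$members
             else as.character(subset)
  writeLines(members, path)
  invisible(path)
}
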