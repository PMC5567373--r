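# Independent oracles used across the suite. These deliberately avoid the
# implementation paths they check (no igraph, no closed-form LOO shortcuts).

# Brute-force clustering coefficient from a symmetric 0/1 adjacency matrix:
# count edges among every pair of neighbours of node i.
bf_clustering <- function(adj, i) {
  nb <- which(adj[i, ] == 1)
  n <- length(nb)
  if (n < 2) return(0)
  e <- 0
  for (a in seq_len(n - 1)) for (b in seq(a + 1, n))
    e <- e + adj[nb[a], nb[b]]
  2 * e / (n * (n - 1))
}

# Random simple undirected graph as an adjacency matrix (base R only).
random_adjacency <- function(n, p = 0.3) {
  adj <- matrix(0L, n, n)
  for (a in seq_len(n - 1)) for (b in seq(a + 1, n))
    if (stats::runif(1) < p) adj[a, b] <- adj[b, a] <- 1L
  dimnames(adj) <- list(paste0("N", seq_len(n)), paste0("N", seq_len(n)))
  adj
}

graph_from_adj <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

# Explicit leave-one-out loop around an arbitrary fit/predict pair.
bf_loo_pred <- function(X, y, fit_fun, pred_fun) {
  n <- length(y)
  vapply(seq_len(n), function(i) {
    m <- fit_fun(X[-i, , drop = FALSE], y[-i])
    pred_fun(m, X[i, , drop = FALSE])
  }, numeric(1))
}

# All non-empty subsets of a name vector (for exhaustive best-subset search).
all_subsets <- function(names) {
  k <- length(names)
  out <- list()
  for (mask in seq_len(2^k - 1)) {
    bits <- as.logical(bitwAnd(mask, 2^(seq_len(k) - 1)))
    out[[length(out) + 1]] <- names[bits]
  }
  out
}

# Small deterministic regression fixture: y linear in 2 of k columns + noise.
toy_regression <- function(n = 15, k = 4, noise = 0.1, seed = 42) {
  set.seed(seed)
  X <- matrix(rnorm(n * k), n, k,
              dimnames = list(NULL, paste0("V", seq_len(k))))
  y <- 1.5 * X[, 1] - X[, 2] + rnorm(n, 0, noise)
  list(X = X, y = y)
}

# Dataset for Table-style pathway deviation checks, built from the packaged
# reference rows.
fixture_dataset <- function() {
  fx <- mpf_deviation_fixture()
  eco <- !is.na(fx$neg_log_c_eco)
  sce <- !is.na(fx$neg_log_c_sce)
  metabolite_dataset(
    metabolite_id = c(fx$name[eco], fx$name[sce]),
    organism = c(rep("eco", sum(eco)), rep("sce", sum(sce))),
    neg_log_c = c(fx$neg_log_c_eco[eco], fx$neg_log_c_sce[sce]))
}
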