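# Shared fixtures built in code.

# tiny complete panel: n areas x np periods with deterministic counts
tiny_panel <- function(n = 4, np = 3, seed = 1) {
  set.seed(seed)
  areal_panel(
    area_ids = paste0("a", seq_len(n)),
    periods = 2007:(2006 + np),
    counts = matrix(rpois(n * np, 20), n, np),
    population = matrix(1e5 * exp(rnorm(n * np, 0, 0.1)), n, np),
    covariates = list(
      x1 = matrix(rnorm(n * np, 10, 2), n, np),
      x2 = rnorm(n, 5, 1)))
}

# weights object from an explicit symmetric edge list
edge_weights <- function(n, edges, ids = paste0("a", seq_len(n))) {
  nb <- rep(list(integer(0)), n)
  for (e in edges) {
    nb[[e[1]]] <- c(nb[[e[1]]], e[2])
    nb[[e[2]]] <- c(nb[[e[2]]], e[1])
  }
  spatial_weights(ids, nb)
}

# path graph a1 - a2 - ... - an
path_weights <- function(n) {
  edge_weights(n, lapply(seq_len(n - 1), function(i) c(i, i + 1)))
}

# complete graph K_n
complete_weights <- function(n) {
  edge_weights(n, do.call(c, lapply(seq_len(n - 1), function(i) {
    lapply((i + 1):n, function(j) c(i, j))
  })))
}

# random symmetric graph with ~p edge density (never empty rows forced)
random_weights <- function(n, p = 0.15, seed = 1) {
  set.seed(seed)
  edges <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (runif(1) < p) edges[[length(edges) + 1L]] <- c(i, j)
    }
  }
  if (!length(edges)) edges <- list(c(1, 2))
  edge_weights(n, edges)
}

# O(n^2) brute-force Moran double sum from the dense weight matrix
dense_W <- function(w) {
  W <- matrix(0, w$n, w$n)
  for (i in seq_len(w$n)) W[i, w$neighbors[[i]]] <- w$weights[[i]]
  W
}

brute_moran <- function(values, w) {
  z <- values - mean(values)
  W <- dense_W(w)
  (w$n / sum(W)) * sum(outer(z, z) * W) / sum(z^2)
}

brute_bivariate_moran <- function(x, y, w) {
  zx <- x - mean(x); zy <- y - mean(y)
  W <- dense_W(w)
  (w$n / sum(W)) * sum(outer(zx, zy) * W) / (sqrt(sum(zx^2)) * sqrt(sum(zy^2)))
}

# small simulation scenario for fast model fits
small_scenario <- function(rows = 8, cols = 8, ...) {
  sim_scenario(rows = rows, cols = cols, ...)
}

full_spec <- function(family = "model1a", ...) {
  model_spec(family,
             covariates = c("income", "unemployment", "density", "depression",
                            "gp", "psychiatrists", "psychotherapists"),
             transforms = c(density = "log"), ...)
}
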