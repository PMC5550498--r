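#' Event rates per head of population
#'
#' Annual rates per `per` persons: `rate_it = per * y_it / P_it`.
#'
#' @param panel an [areal_panel()].
#' @param per denominator scale (default 100,000 persons).
#' @param period optional single period label; if given, returns the rate
#'   vector for that period only.
#' @return matrix (areas x periods) of rates, or a vector if `period` given.
#' @export
event_rate <- function(panel, per = 1e5, period = NULL) {
  stopifnot(inherits(panel, "areal_panel"), per > 0)
  r <- per * panel$counts / panel$population
  if (!is.null(period)) {
    j <- match(as.integer(period), panel$periods)
    if (is.na(j)) stop("period ", period, " not in panel")
    return(stats::setNames(r[, j], panel$area_ids))
  }
  r
}

# spatial lag W z with list weights; islands produce zero
spatial_lag <- function(z, w) {
  vapply(seq_len(w$n), function(i) {
    nb <- w$neighbors[[i]]
    if (!length(nb)) 0 else sum(w$weights[[i]] * z[nb])
  }, numeric(1))
}

#' Global Moran's I
#'
#' `I = (n / S0) * (z' W z) / (z' z)` with `z` the mean-centred values and
#' `S0` the total weight. Islands contribute nothing to the numerator but are
#' retained in `n`. Positive values indicate that similar values cluster in
#' space; the expectation under exchangeability is `-1/(n-1)`.
#'
#' @param values numeric vector over areas (non-constant).
#' @param w a [spatial_weights()] object, typically row-standardised.
#' @return Moran's I (scalar).
#' @export
morans_i <- function(values, w) {
  stopifnot(inherits(w, "spatial_weights"), length(values) == w$n)
  z <- values - mean(values)
  szz <- sum(z^2)
  if (szz == 0) stop("zero variance: Moran's I undefined for a constant vector")
  s0 <- sum(unlist(w$weights))
  if (s0 <= 0) stop("weights sum to zero")
  (w$n / s0) * sum(z * spatial_lag(z, w)) / szz
}

#' Bivariate Moran's I
#'
#' Spatial cross-correlation between one variable and the spatial lag of
#' another (here typically the same rate one period later):
#' `I = (n / S0) * (z_x' W z_y) / (||z_x|| ||z_y||)`, each vector centred.
#' With `y = x` this reduces exactly to [morans_i()].
#'
#' @param x,y numeric vectors over areas (both non-constant).
#' @param w a [spatial_weights()] object.
#' @return bivariate Moran's I (scalar).
#' @export
bivariate_morans_i <- function(x, y, w) {
  stopifnot(inherits(w, "spatial_weights"),
            length(x) == w$n, length(y) == w$n)
  zx <- x - mean(x); zy <- y - mean(y)
  nx <- sqrt(sum(zx^2)); ny <- sqrt(sum(zy^2))
  if (nx == 0 || ny == 0) stop("zero variance: constant input vector")
  s0 <- sum(unlist(w$weights))
  (w$n / s0) * sum(zx * spatial_lag(zy, w)) / (nx * ny)
}

#' Permutation test for (bivariate) Moran's I
#'
#' Pseudo p-value against the null of spatial randomness from `n_perm` random
#' relabellings: `p = (r + 1) / (n_perm + 1)` where `r` counts permuted
#' statistics at least as extreme as the observed one, on the side of the
#' observed deviation from the null expectation `-1/(n-1)`. For the bivariate
#' statistic only `y` is permuted while the map of `x` stays fixed, so the
#' test targets space-time alignment.
#'
#' @param x numeric vector over areas.
#' @param w a [spatial_weights()] object.
#' @param y optional second vector; if supplied the bivariate statistic is
#'   tested.
#' @param n_perm number of permutations (the conventional choice is 9,999,
#'   giving a p-value floor of 1e-4).
#' @param seed integer seed for reproducibility.
#' @return list of class `moran_test`: `statistic`, `expectation`
#'   (`-1/(n-1)`), `pseudo_p`, `n_permutations`, `seed`, `kind`, and the
#'   permuted statistics in `permuted`.
#' @export
moran_test <- function(x, w, y = NULL, n_perm = 9999, seed = 1L) {
  stopifnot(n_perm >= 1)
  kind <- if (is.null(y)) "univariate" else "bivariate"
  obs <- if (is.null(y)) morans_i(x, w) else bivariate_morans_i(x, y, w)
  e_i <- -1 / (w$n - 1)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(b) {
    if (is.null(y)) {
      morans_i(sample(x), w)
    } else {
      bivariate_morans_i(x, sample(y), w)
    }
  }, numeric(1))
  r <- if (obs >= e_i) sum(perm >= obs) else sum(perm <= obs)
  structure(list(statistic = obs, expectation = e_i,
                 pseudo_p = (r + 1) / (n_perm + 1),
                 n_permutations = n_perm, seed = seed, kind = kind,
                 permuted = perm),
            class = "moran_test")
}

#' @export
print.moran_test <- function(x, ...) {
  cat(sprintf("%s Moran's I = %.4f (E[I] = %.4f), pseudo-p = %.4g [%d permutations]\n",
              x$kind, x$statistic, x$expectation, x$pseudo_p,
              x$n_permutations))
  invisible(x)
}

#' Spearman correlation matrix for covariate screening
#'
#' Tie-corrected (average-rank) Spearman correlations between covariates,
#' flattened over all area-period cells; the standard multicollinearity
#' screen before an ecological regression. A constant covariate yields NA in
#' its row/column with a warning.
#'
#' @param panel an [areal_panel()] with at least two covariates, or a named
#'   list of equally-sized matrices/vectors.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(panel) {
  covs <- if (inherits(panel, "areal_panel")) panel$covariates else panel
  if (length(covs) < 2) stop("need at least two covariates")
  mat <- vapply(covs, function(x) as.vector(as.matrix(x)),
                numeric(length(as.vector(as.matrix(covs[[1]])))))
  if (nrow(mat) < 3) stop("need at least 3 observations")
  const <- apply(mat, 2, function(x) stats::sd(x) == 0)
  rho <- suppressWarnings(stats::cor(mat, method = "spearman"))
  if (any(const)) {
    warning("constant covariate(s): ",
            paste(colnames(mat)[const], collapse = ", "))
    rho[const, ] <- NA_real_
    rho[, const] <- NA_real_
  }
  diag(rho) <- 1
  rho
}

#' Run the full exploratory battery on a panel
#'
#' Per-period univariate Moran tests on event rates and per-(t, t+1)
#' bivariate Moran tests, mirroring the standard pre-modelling workflow for
#' areal incidence panels.
#'
#' @param panel an [areal_panel()].
#' @param w a [spatial_weights()] object (row-standardised internally).
#' @param n_perm permutations per test.
#' @param seed base seed; each test uses an offset sub-seed.
#' @param per rate denominator.
#' @return list with data frames `univariate` and `bivariate`.
#' @export
explore_panel <- function(panel, w, n_perm = 9999, seed = 1L, per = 1e5) {
  if (w$style != "row_standardized") w <- row_standardize(w)
  rates <- event_rate(panel, per = per)
  np <- length(panel$periods)
  uni <- do.call(rbind, lapply(seq_len(np), function(j) {
    mt <- moran_test(rates[, j], w, n_perm = n_perm, seed = seed + j)
    data.frame(period = panel$periods[j], I = mt$statistic,
               pseudo_p = mt$pseudo_p)
  }))
  biv <- NULL
  if (np > 1) {
    biv <- do.call(rbind, lapply(seq_len(np - 1L), function(j) {
      mt <- moran_test(rates[, j], w, y = rates[, j + 1L],
                       n_perm = n_perm, seed = seed + 100L + j)
      data.frame(period_t = panel$periods[j],
                 period_t1 = panel$periods[j + 1L],
                 I = mt$statistic, pseudo_p = mt$pseudo_p)
    }))
  }
  list(univariate = uni, bivariate = biv)
}
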