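#' Gaussian Markov random field structure matrices
#'
#' A `gmrf_structure` bundles a symmetric positive semi-definite precision
#' structure matrix `Q` with its declared rank deficiency, the linear
#' sum-to-zero constraints that identify the field, and the variance scaling
#' factor applied by [scale_structure()]. The three kinds used by the
#' space-time models are the intrinsic CAR over the area graph
#' ([icar_structure()]), the second-order random walk over ordered levels
#' ([rw2_structure()]), and the exchangeable iid field ([iid_structure()]).
#'
#' @name gmrf_structure
NULL

new_gmrf <- function(Q, rank_def, constraints, kind, scale_factor = 1) {
  m <- nrow(Q)
  stopifnot(ncol(Q) == m)
  if (m > 0 && max(abs(Q - t(Q))) > 1e-12 * max(1, max(abs(Q)))) {
    stop("structure matrix not symmetric")
  }
  structure(list(Q = Q, m = m, rank_deficiency = as.integer(rank_def),
                 constraints = constraints, kind = kind,
                 scale_factor = scale_factor),
            class = "gmrf_structure")
}

#' @export
print.gmrf_structure <- function(x, ...) {
  cat(sprintf("GMRF structure [%s]: m = %d, rank deficiency = %d, %d constraint(s), scale factor = %.6g\n",
              x$kind, x$m, x$rank_deficiency,
              if (is.null(x$constraints)) 0L else nrow(x$constraints),
              x$scale_factor))
  invisible(x)
}

#' Intrinsic CAR structure from a binary adjacency
#'
#' `Q = D - A` (degree matrix minus adjacency), the precision structure of
#' the intrinsic conditional autoregressive prior in which each area effect
#' is conditionally centred on the mean of its neighbours. Rank deficiency
#' equals the number of connected components; the constraints are one
#' sum-to-zero row per component. Islands form singleton components with a
#' zero diagonal entry and a point constraint.
#'
#' @param w a binary [spatial_weights()] object.
#' @return a `gmrf_structure` of kind `"icar"`.
#' @export
icar_structure <- function(w) {
  stopifnot(inherits(w, "spatial_weights"))
  if (w$style != "binary") stop("icar_structure needs binary adjacency")
  n <- w$n
  Q <- matrix(0, n, n, dimnames = list(w$ids, w$ids))
  for (i in seq_len(n)) {
    nb <- w$neighbors[[i]]
    Q[i, i] <- length(nb)
    Q[i, nb] <- -1
  }
  ncomp <- max(w$components)
  A <- matrix(0, ncomp, n)
  for (k in seq_len(ncomp)) A[k, w$components == k] <- 1
  new_gmrf(Q, rank_def = ncomp, constraints = A, kind = "icar")
}

#' Second-order random walk structure
#'
#' `Q = D' D` with `D` the (m-2) x m second-difference operator: the
#' smoothness prior penalising curvature, whose null space contains the
#' constant and linear sequences (rank deficiency 2). One sum-to-zero
#' constraint is declared; the linear null direction is left to be
#' identified by the likelihood, as is conventional for RW2 effects.
#'
#' @param m number of ordered levels (at least 3).
#' @return a `gmrf_structure` of kind `"rw2"`.
#' @export
rw2_structure <- function(m) {
  if (m < 3) stop("RW2 needs at least 3 levels")
  D <- matrix(0, m - 2L, m)
  for (k in seq_len(m - 2L)) D[k, k + 0:2] <- c(1, -2, 1)
  new_gmrf(crossprod(D), rank_def = 2L,
           constraints = matrix(1, 1, m), kind = "rw2")
}

#' Exchangeable iid structure
#'
#' Identity precision structure with full rank and no constraints; the
#' unstructured half of the BYM convolution and the prior for the
#' differential-trend and unstructured-time fields.
#'
#' @param m dimension.
#' @param constrained if `TRUE`, declare a sum-to-zero constraint (used for
#'   fields that are identified only up to a level, e.g. differential
#'   slopes).
#' @return a `gmrf_structure` of kind `"iid"`.
#' @export
iid_structure <- function(m, constrained = FALSE) {
  new_gmrf(diag(m), rank_def = 0L,
           constraints = if (constrained) matrix(1, 1, m) else NULL,
           kind = "iid")
}

# eigendecomposition with the null space identified by rank deficiency
gmrf_eigen <- function(s) {
  e <- eigen(s$Q, symmetric = TRUE)
  lam <- rev(e$values)
  vec <- e$vectors[, rev(seq_len(s$m)), drop = FALSE]
  pos <- seq_len(s$m) > s$rank_deficiency
  list(values = lam, vectors = vec, pos = pos)
}

# marginal variances of the constrained generalized inverse of Q
# (pseudo-inverse over the positive eigenspace; null space constrained out)
gmrf_marginal_var <- function(s) {
  if (s$m == 0) stop("empty structure")
  e <- gmrf_eigen(s)
  lam <- e$values[e$pos]
  V <- e$vectors[, e$pos, drop = FALSE]
  rowSums(sweep(V^2, 2, lam, "/"))
}

#' Scale a GMRF structure to unit typical marginal variance
#'
#' Multiplies `Q` by the geometric mean of the marginal variances of its
#' constrained generalized inverse, so that afterwards that geometric mean is
#' 1. This makes a single precision hyperprior comparable across structures
#' of different graphs and sizes (the standard "scaled" hyperprior
#' convention). Entries with zero marginal variance (islands under a point
#' constraint) are excluded from the geometric mean. Idempotent.
#'
#' @param s a `gmrf_structure`.
#' @return the scaled `gmrf_structure`, with `scale_factor` recording the
#'   cumulative multiplier.
#' @export
scale_structure <- function(s) {
  stopifnot(inherits(s, "gmrf_structure"))
  if (s$m == 0) stop("empty structure")
  mv <- gmrf_marginal_var(s)
  mv <- mv[mv > 1e-12 * max(mv, 1)]
  if (!length(mv)) return(s)  # all point-constrained: nothing to scale
  g <- exp(mean(log(mv)))
  out <- s
  out$Q <- s$Q * g
  out$scale_factor <- s$scale_factor * g
  out
}

#' Sample a constrained zero-mean GMRF
#'
#' Draws from `N(0, (tau * Q)^-)` restricted to the subspace orthogonal to
#' the null space of `Q` (conditioning by kriging on the eigenbasis), so
#' every declared sum-to-zero constraint holds exactly. Deterministic given
#' `seed`.
#'
#' @param s a `gmrf_structure`.
#' @param tau precision multiplier (positive).
#' @param seed optional integer seed.
#' @return numeric vector of length `m` with `A x = 0` for every declared
#'   constraint row.
#' @export
sample_constrained <- function(s, tau, seed = NULL) {
  stopifnot(inherits(s, "gmrf_structure"))
  if (tau <= 0) stop("tau must be positive")
  if (!is.null(seed)) set.seed(seed)
  e <- gmrf_eigen(s)
  lam <- e$values[e$pos]
  V <- e$vectors[, e$pos, drop = FALSE]
  z <- stats::rnorm(length(lam))
  x <- as.vector(V %*% (z / sqrt(tau * lam)))
  # constraints lying outside the null space are enforced by kriging
  A <- s$constraints
  if (!is.null(A) && nrow(A)) {
    r <- A %*% x
    if (max(abs(r)) > 1e-10) {
      Sig <- V %*% (t(V) / (tau * lam))
      SA <- Sig %*% t(A)
      M <- A %*% SA
      x <- x - as.vector(SA %*% solve(M, r))
    }
  }
  x
}

#' Quadratic form x' Q x of a structure
#'
#' @param s a `gmrf_structure`.
#' @param x numeric vector of length `m`.
#' @return scalar `x' Q x` (non-negative).
#' @export
quad_form <- function(s, x) {
  stopifnot(length(x) == s$m)
  as.numeric(crossprod(x, s$Q %*% x))
}
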