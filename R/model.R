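#' Declare a space-time Poisson model
#'
#' The five model families share a BYM convolution (spatially structured
#' ICAR effect `u_i` plus unstructured effect `v_i`) on top of a log-linear
#' Poisson regression with an internally standardised expected-count offset.
#' They differ in the temporal term and in the covariate roles:
#'
#' * `null_parametric` -- no covariates; grand linear trend `gamma` plus
#'   area-specific differential slopes `delta_i` (sum-to-zero, exchangeable).
#' * `null_dynamic` -- no covariates; non-parametric trend: RW2 period
#'   effect `phi_t` plus iid period effect `psi_t`.
#' * `model1a` -- parametric trend as above; all included covariates linear.
#' * `model1b` -- parametric trend (the period slope stays linear); the
#'   covariates named in `nonlinear` are replaced by RW2 effects over binned
#'   covariate values, the rest stay linear.
#' * `model2` -- dynamic RW2 + iid trend; all covariates linear.
#'
#' @param family one of `"null_parametric"`, `"null_dynamic"`, `"model1a"`,
#'   `"model1b"`, `"model2"`.
#' @param covariates character vector of covariate names entering the model
#'   (ignored, and must be empty, for the null families).
#' @param nonlinear subset of `covariates` modelled as RW2 (model1b only).
#' @param bins number of equally spaced bins for each RW2 covariate effect.
#' @param transforms named character vector of per-covariate transforms
#'   applied before use; currently `"log"` (e.g. population density).
#' @param time_centering reference period subtracted from the period label
#'   to form the time index `t~`; default: the middle period, so a slope
#'   `gamma` is the log relative risk per period at the panel midpoint.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(family = c("model1a", "model1b", "model2",
                                  "null_parametric", "null_dynamic"),
                       covariates = character(0),
                       nonlinear = character(0),
                       bins = 100L,
                       transforms = character(0),
                       time_centering = NULL) {
  family <- match.arg(family)
  covariates <- as.character(covariates)
  nonlinear <- as.character(nonlinear)
  if (family %in% c("null_parametric", "null_dynamic") && length(covariates)) {
    stop("null families include no covariates")
  }
  if (length(nonlinear)) {
    if (family != "model1b") stop("nonlinear covariates require family model1b")
    if (!all(nonlinear %in% covariates)) {
      stop("nonlinear names must be a subset of covariates")
    }
  }
  if (family == "model1b" && !length(nonlinear)) {
    stop("model1b needs at least one nonlinear covariate")
  }
  trend <- if (family %in% c("null_dynamic", "model2")) "rw2_dynamic"
           else "linear_differential"
  roles <- stats::setNames(rep("linear", length(covariates)), covariates)
  roles[nonlinear] <- "rw2"
  structure(list(family = family, covariates = covariates,
                 covariate_roles = roles, nonlinear = nonlinear,
                 bins = as.integer(bins), transforms = transforms,
                 trend = trend, offset_mode = "expected_counts",
                 time_centering = time_centering),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Space-time Poisson model spec [", x$family, "], trend =", x$trend, "\n")
  if (length(x$covariates)) {
    cat("  covariates:",
        paste0(x$covariates, " (", x$covariate_roles[x$covariates], ")",
               collapse = ", "), "\n")
  }
  invisible(x)
}

# resolve the time-centering reference and centred time index per period
time_index <- function(spec, panel) {
  ref <- spec$time_centering
  if (is.null(ref)) ref <- panel$periods[(length(panel$periods) + 1L) %/% 2L]
  panel$periods - ref
}

# covariate matrix after the declared transform
transformed_covariate <- function(spec, panel, nm) {
  x <- panel$covariates[[nm]]
  if (is.null(x)) stop("covariate '", nm, "' not in panel")
  tr <- spec$transforms[nm]
  if (!is.na(tr) && length(tr) && identical(unname(tr), "log")) {
    if (any(x <= 0)) stop("log transform of non-positive covariate '", nm, "'")
    x <- log(x)
  }
  x
}

#' Bin a covariate onto equally spaced levels
#'
#' RW2 covariate effects live on `m` equally spaced bins spanning the
#' observed (or supplied) range; each observation maps to the bin whose
#' midpoint is nearest. Values outside the range are clamped to the boundary
#' bin with a warning.
#'
#' @param x numeric vector or matrix of covariate values.
#' @param m number of bins.
#' @param range length-2 numeric; defaults to `range(x)`.
#' @return list with `index` (integer, same shape as `x`), `midpoints`
#'   (length `m`) and `range`.
#' @export
bin_covariate <- function(x, m = 100L, range = NULL) {
  if (is.null(range)) range <- base::range(x)
  lo <- range[1]; hi <- range[2]
  if (!(hi > lo)) stop("degenerate covariate range")
  width <- (hi - lo) / m
  j <- floor((x - lo) / width) + 1L
  if (any(x < lo | x > hi)) {
    warning("covariate values outside bin range clamped to boundary bins")
  }
  j[j < 1L] <- 1L
  j[j > m] <- m
  idx <- x  # preserve matrix shape
  idx[] <- j
  storage.mode(idx) <- "integer"
  list(index = idx, midpoints = lo + (seq_len(m) - 0.5) * width,
       range = c(lo, hi))
}

# binning for every rw2 covariate of a spec
spec_binning <- function(spec, panel) {
  out <- list()
  for (nm in spec$nonlinear) {
    out[[nm]] <- bin_covariate(transformed_covariate(spec, panel, nm),
                               m = spec$bins)
  }
  out
}

#' Internally standardised expected counts
#'
#' `E_it = P_it * (sum(y) / sum(P))`: the offset that makes all fitted
#' relative risks relative to the panel-wide average rate, so `exp(alpha)`
#' is close to 1 and area summaries read as "compared to the whole study
#' region". Conserves the total: `sum(E) = sum(y)` exactly.
#'
#' @param panel an [areal_panel()].
#' @return matrix (areas x periods) of expected counts.
#' @export
expected_counts <- function(panel) {
  stopifnot(inherits(panel, "areal_panel"))
  tot <- sum(panel$counts)
  if (tot == 0) stop("all counts zero: overall rate undefined")
  panel$population * (tot / sum(panel$population))
}

#' Assemble the linear predictor
#'
#' `eta_it = alpha + sum_k beta_k x_itk + sum_k f_k[bin(x_itk)] + u_i + v_i
#' + trend_it`, where the trend is `(gamma + delta_i) * t~` for the
#' parametric families (centred time index `t~`) or `phi_t + psi_t` for the
#' dynamic families. Missing state components are treated as zero.
#'
#' @param spec a [model_spec()].
#' @param state named list of latent components: `alpha`, `beta` (named),
#'   `gamma`, `delta`, `u`, `v`, `f` (named list of bin-effect vectors),
#'   `phi`, `psi`.
#' @param panel an [areal_panel()].
#' @param binning optional precomputed [bin_covariate()] list per rw2
#'   covariate (computed from the panel when absent).
#' @return matrix (areas x periods) of log relative risks.
#' @export
linear_predictor <- function(spec, state, panel, binning = NULL) {
  n <- length(panel$area_ids); np <- length(panel$periods)
  eta <- matrix(if (is.null(state$alpha)) 0 else state$alpha, n, np)
  for (nm in spec$covariates) {
    if (spec$covariate_roles[[nm]] == "linear") {
      b <- state$beta[[nm]]
      if (!is.null(b) && b != 0) {
        eta <- eta + b * transformed_covariate(spec, panel, nm)
      }
    }
  }
  if (length(spec$nonlinear)) {
    if (is.null(binning)) binning <- spec_binning(spec, panel)
    for (nm in spec$nonlinear) {
      f <- state$f[[nm]]
      if (!is.null(f)) {
        idx <- binning[[nm]]$index
        eta <- eta + matrix(f[idx], n, np)
      }
    }
  }
  if (!is.null(state$u)) eta <- eta + matrix(state$u, n, np)
  if (!is.null(state$v)) eta <- eta + matrix(state$v, n, np)
  if (spec$trend == "linear_differential") {
    tt <- time_index(spec, panel)
    slope <- if (is.null(state$gamma)) 0 else state$gamma
    sl <- rep(slope, n) + (if (is.null(state$delta)) 0 else state$delta)
    eta <- eta + outer(sl, tt)
  } else {
    ph <- if (is.null(state$phi)) rep(0, np) else state$phi
    ps <- if (is.null(state$psi)) rep(0, np) else state$psi
    eta <- eta + matrix(ph + ps, n, np, byrow = TRUE)
  }
  dimnames(eta) <- dimnames(panel$counts)
  eta
}

#' Poisson log-likelihood of a count panel
#'
#' `sum_it [ y log(E e^eta) - E e^eta - log(y!) ]`.
#'
#' @param y counts matrix.
#' @param E expected-count offset matrix (positive).
#' @param eta linear predictor matrix.
#' @return scalar log-likelihood.
#' @export
poisson_loglik <- function(y, E, eta) {
  stopifnot(all(dim(y) == dim(E)), all(dim(y) == dim(eta)))
  if (any(!is.finite(eta)) || any(!is.finite(E)) || any(E <= 0)) {
    stop("non-finite linear predictor or non-positive offset")
  }
  sum(stats::dpois(y, lambda = E * exp(eta), log = TRUE))
}
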