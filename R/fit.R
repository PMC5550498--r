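#' Hyperpriors for the precision parameters
#'
#' Each random-effect precision tau gets a Gamma(shape a, rate b) prior.
#' The default Gamma(1, 5e-5) is the conventional diffuse choice for scaled
#' structures in Bayesian disease mapping: because every GMRF structure is
#' scaled to unit typical marginal variance, one prior is comparable across
#' the spatial, differential-trend, random-walk and iid fields.
#'
#' @param a,b default shape and rate applied to every precision.
#' @param ... per-field overrides as length-2 vectors `c(a, b)`; recognised
#'   names: `u`, `v`, `delta`, `phi`, `psi`, `f`.
#' @return named list of `c(a, b)` pairs, class `hyperpriors`.
#' @export
hyperpriors <- function(a = 1, b = 5e-5, ...) {
  if (a <= 0 || b <= 0) stop("Gamma hyperparameters must be positive")
  out <- stats::setNames(rep(list(c(a = a, b = b)), 6),
                         c("u", "v", "delta", "phi", "psi", "f"))
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(out)) stop("unknown precision field: ", nm)
    p <- dots[[nm]]
    if (length(p) != 2 || any(p <= 0)) stop("override must be positive c(a, b)")
    out[[nm]] <- c(a = p[1], b = p[2])
  }
  structure(out, class = "hyperpriors")
}

#' MCMC settings
#'
#' @param n_iter total iterations (including burn-in).
#' @param burnin iterations discarded; adaptation of the single-site
#'   random-walk proposals (target acceptance 0.44) happens only here and is
#'   frozen afterwards.
#' @param thin store every `thin`-th post-burn-in draw.
#' @param seed integer seed; the whole chain is deterministic given it.
#' @return list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 15000L, burnin = 5000L, thin = 10L,
                        seed = 1L) {
  n_iter <- as.integer(n_iter); burnin <- as.integer(burnin)
  thin <- as.integer(thin)
  if (!(n_iter > burnin && burnin >= 0L && thin >= 1L)) {
    stop("need n_iter > burnin >= 0 and thin >= 1")
  }
  structure(list(n_iter = n_iter, burnin = burnin, thin = thin,
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

# split-chain potential scale reduction factor on a single stored series
split_rhat <- function(x) {
  S <- length(x) %/% 2L
  if (S < 2L) return(NA_real_)
  halves <- list(x[seq_len(S)], x[S + seq_len(S)])
  m <- vapply(halves, mean, numeric(1))
  v <- vapply(halves, stats::var, numeric(1))
  W <- mean(v)
  B <- S * stats::var(m)
  if (W <= 0) return(1)
  sqrt(((S - 1) / S * W + B / S) / W)
}

#' Fit a Bayesian space-time Poisson model
#'
#' Fits the hierarchy declared by a [model_spec()] to an areal count panel by
#' adaptive Metropolis-within-Gibbs: single-site Gaussian random-walk updates
#' for the intercept, covariate coefficients, trend components, BYM residuals
#' and RW2 bin effects, with conjugate Gamma updates for every precision and
#' sum-to-zero re-projection after each block sweep (compensated so the
#' linear predictor is unchanged). All GMRF structures are scaled to unit
#' typical marginal variance before fitting, so the common hyperprior is
#' comparable across fields.
#'
#' @param panel an [areal_panel()].
#' @param weights a [spatial_weights()] object over the panel's areas
#'   (binary or row-standardised; the ICAR structure uses the binary
#'   adjacency).
#' @param spec a [model_spec()].
#' @param priors a [hyperpriors()] object.
#' @param mcmc an [mcmc_config()].
#' @param include_residual include the BYM convolution `u + v`? Setting
#'   `FALSE` gives a fixed-effects-only Poisson regression (useful for
#'   small-panel checks against exact posteriors).
#' @param offset optional matrix of expected counts `E_it` to use instead of
#'   the internally standardised [expected_counts()] (e.g. externally
#'   age-standardised expectations).
#' @return An object of class `stpois`: stored posterior draws for every
#'   latent component and precision, the spec/panel/weights that produced
#'   them, acceptance rates, split-chain Rhat for the fixed effects, and the
#'   DIC. Methods: [summary.stpois()], [coef.stpois()], `fitted`,
#'   `residuals`, `simulate`, `plot`.
#' @export
stpois <- function(panel, weights, spec = model_spec(),
                   priors = hyperpriors(), mcmc = mcmc_config(),
                   include_residual = TRUE, offset = NULL) {
  stopifnot(inherits(panel, "areal_panel"),
            inherits(weights, "spatial_weights"),
            inherits(spec, "model_spec"))
  if (weights$n != length(panel$area_ids)) {
    stop("weights and panel disagree on the number of areas")
  }
  if (!identical(weights$ids, panel$area_ids)) {
    stop("weights and panel area ids differ (order matters)")
  }
  miss <- setdiff(spec$covariates, names(panel$covariates))
  if (length(miss)) stop("covariates not in panel: ", paste(miss, collapse = ", "))
  n <- length(panel$area_ids); np <- length(panel$periods)
  if (spec$trend == "rw2_dynamic" && np < 3) {
    stop("dynamic trend needs at least 3 periods")
  }

  E <- if (is.null(offset)) expected_counts(panel) else {
    stopifnot(all(dim(offset) == dim(panel$counts)), all(offset > 0))
    offset
  }
  wbin <- if (weights$style == "binary") weights
          else spatial_weights(weights$ids, weights$neighbors, "binary")
  icar <- scale_structure(icar_structure(wbin))

  lin <- spec$covariates[spec$covariate_roles[spec$covariates] == "linear"]
  Xlin <- lapply(lin, function(nm) transformed_covariate(spec, panel, nm))
  names(Xlin) <- lin
  # centre covariates for sampling (decorrelates beta from alpha); the
  # intercept draws are mapped back to the raw-covariate scale afterwards
  xmeans <- vapply(Xlin, mean, numeric(1))
  Xlin <- lapply(seq_along(Xlin), function(k) Xlin[[k]] - xmeans[k])
  binning <- spec_binning(spec, panel)
  fbin_cells <- lapply(binning, function(bn) {
    idx <- as.vector(bn$index)
    lapply(seq_along(bn$midpoints), function(j) which(idx == j) - 1L)
  })
  Qf <- lapply(binning, function(bn) {
    scale_structure(rw2_structure(length(bn$midpoints)))$Q
  })
  Qphi <- NULL
  if (spec$trend == "rw2_dynamic") {
    Qphi <- scale_structure(rw2_structure(np))$Q
  }

  prior_list <- list(
    a_u = priors$u[1], b_u = priors$u[2],
    a_v = priors$v[1], b_v = priors$v[2],
    a_delta = priors$delta[1], b_delta = priors$delta[2],
    a_phi = priors$phi[1], b_phi = priors$phi[2],
    a_psi = priors$psi[1], b_psi = priors$psi[2],
    a_f = rep(priors$f[1], length(Qf)), b_f = rep(priors$f[2], length(Qf)))

  set.seed(mcmc$seed)
  res <- .st_mcmc(panel$counts, E, unname(Xlin), unname(fbin_cells),
                  unname(Qf), lapply(weights$neighbors, function(x) x - 1L),
                  weights$components - 1L, icar$scale_factor, Qphi,
                  as.numeric(time_index(spec, panel)),
                  spec$trend == "linear_differential", include_residual,
                  0.001, prior_list, mcmc$n_iter, mcmc$burnin, mcmc$thin)

  colnames(res$beta) <- lin
  if (length(lin)) {
    res$alpha <- res$alpha - as.vector(res$beta %*% xmeans)
  }
  names(res$f) <- names(binning)
  names(res$tau_f) <- names(binning)
  colnames(res$delta) <- panel$area_ids
  colnames(res$u) <- panel$area_ids
  colnames(res$v) <- panel$area_ids

  rhat <- c(alpha = split_rhat(res$alpha))
  for (nm in lin) rhat[paste0("beta.", nm)] <- split_rhat(res$beta[, nm])
  if (spec$trend == "linear_differential") {
    rhat["gamma"] <- split_rhat(res$gamma)
  }

  fit <- structure(list(draws = res, spec = spec, panel = panel,
                        weights = weights, binning = binning, E = E,
                        icar_scale = icar$scale_factor,
                        include_residual = include_residual,
                        priors = priors, mcmc = mcmc,
                        acceptance = res$acceptance, rhat = rhat),
                   class = "stpois")
  fit$dic <- dic(fit)
  fit
}

# reconstruct the state list of one stored draw
draw_state <- function(fit, s) {
  d <- fit$draws
  list(alpha = d$alpha[s],
       beta = as.list(d$beta[s, , drop = TRUE]),
       gamma = d$gamma[s],
       delta = d$delta[s, ],
       u = if (fit$include_residual) d$u[s, ] else NULL,
       v = if (fit$include_residual) d$v[s, ] else NULL,
       f = lapply(d$f, function(m) m[s, ]),
       phi = d$phi[s, ],
       psi = d$psi[s, ])
}

# posterior-mean state; eta is linear in all components, so
# eta(mean state) is the posterior mean linear predictor
mean_state <- function(fit) {
  d <- fit$draws
  list(alpha = mean(d$alpha),
       beta = as.list(colMeans(d$beta)),
       gamma = mean(d$gamma),
       delta = colMeans(d$delta),
       u = if (fit$include_residual) colMeans(d$u) else NULL,
       v = if (fit$include_residual) colMeans(d$v) else NULL,
       f = lapply(d$f, colMeans),
       phi = colMeans(d$phi),
       psi = colMeans(d$psi))
}

#' Deviance information criterion
#'
#' `DIC = Dbar + pD` with `Dbar` the posterior mean deviance
#' (`-2 log L` averaged over draws) and `pD = Dbar - Dhat`, where `Dhat`
#' plugs in the posterior mean of the linear predictor (the latent-field
#' focus conventional in disease mapping). Lower is better.
#'
#' @param object a fitted [stpois()] model, or a list of latent-state lists
#'   (as accepted by [linear_predictor()]).
#' @param ... for the list method: `panel` and `spec` (required), `binning`
#'   optional.
#' @return list of class `dic_result`: `Dbar`, `Dhat`, `pD`, `DIC`.
#' @export
dic <- function(object, ...) UseMethod("dic")

#' @export
dic.stpois <- function(object, ...) {
  Dbar <- mean(object$draws$deviance)
  eta_bar <- linear_predictor(object$spec, mean_state(object), object$panel,
                              object$binning)
  Dhat <- -2 * poisson_loglik(object$panel$counts, object$E, eta_bar)
  structure(list(Dbar = Dbar, Dhat = Dhat, pD = Dbar - Dhat,
                 DIC = Dbar + (Dbar - Dhat)),
            class = "dic_result")
}

#' @export
dic.list <- function(object, panel, spec, binning = NULL, ...) {
  if (length(object) < 2) stop("need at least 2 draws")
  E <- expected_counts(panel)
  etas <- lapply(object, function(st) linear_predictor(spec, st, panel, binning))
  devs <- vapply(etas, function(e) -2 * poisson_loglik(panel$counts, E, e),
                 numeric(1))
  Dbar <- mean(devs)
  eta_bar <- Reduce(`+`, etas) / length(etas)
  Dhat <- -2 * poisson_loglik(panel$counts, E, eta_bar)
  structure(list(Dbar = Dbar, Dhat = Dhat, pD = Dbar - Dhat,
                 DIC = Dbar + (Dbar - Dhat)),
            class = "dic_result")
}

#' @export
print.dic_result <- function(x, ...) {
  cat(sprintf("DIC = %.1f  (Dbar = %.1f, pD = %.1f)\n", x$DIC, x$Dbar, x$pD))
  invisible(x)
}

#' Conjugate precision update
#'
#' Draws from the full conditional of a GMRF precision: with prior
#' Gamma(a, b) and a field `x` under structure `Q` of rank `m - d`, the
#' posterior is `Gamma(a + (m - d)/2, b + x'Qx/2)`.
#'
#' @param field numeric vector satisfying the structure's constraints.
#' @param s a `gmrf_structure`.
#' @param prior length-2 vector `c(a, b)`.
#' @param n number of draws.
#' @param seed optional seed.
#' @return numeric vector of `n` precision draws.
#' @export
update_precision <- function(field, s, prior = c(1, 5e-5), n = 1,
                             seed = NULL) {
  stopifnot(inherits(s, "gmrf_structure"))
  q <- quad_form(s, field)
  if (q < -1e-8) stop("negative quadratic form: structure not PSD")
  q <- max(q, 0)
  if (!is.null(seed)) set.seed(seed)
  stats::rgamma(n, shape = prior[1] + (s$m - s$rank_deficiency) / 2,
                rate = prior[2] + q / 2)
}

rr_row <- function(x) {
  c(RR = exp(mean(x)),
    lower = exp(unname(stats::quantile(x, 0.025))),
    upper = exp(unname(stats::quantile(x, 0.975))))
}

#' Summarise a fitted space-time model
#'
#' Relative risks with 95% credibility intervals for every reported effect:
#' the point estimate is `exp` of the posterior mean coefficient, the CI is
#' `exp` of the posterior 2.5%/97.5% quantiles. Per-area tables give the
#' differential time trend `exp(delta_i)` and the residual relative risk
#' `exp(u_i + v_i)` (summarised draw-wise); per RW2 covariate, the pointwise
#' `exp(f)` curve over bins. An effect has strong statistical support when
#' its 95% CI excludes 1.
#'
#' @param object a fitted [stpois()] model.
#' @param ... unused.
#' @return list of class `summary.stpois` with data frames `fixed`, `areas`,
#'   `curves` (named list), plus `dic`, `acceptance`, `rhat`,
#'   `hyperpriors`.
#' @export
summary.stpois <- function(object, ...) {
  d <- object$draws
  fixed <- rbind(Intercept = rr_row(d$alpha))
  for (nm in colnames(d$beta)) fixed <- rbind(fixed, rr_row(d$beta[, nm]))
  rownames(fixed)[-1] <- colnames(d$beta)
  if (object$spec$trend == "linear_differential") {
    fixed <- rbind(fixed, Year = rr_row(d$gamma))
  }
  fixed <- data.frame(term = rownames(fixed), as.data.frame(fixed),
                      row.names = NULL, check.names = FALSE)

  n <- length(object$panel$area_ids)
  resid_draws <- if (object$include_residual) d$u + d$v
                 else matrix(0, nrow(d$delta), n)
  areas <- data.frame(
    area = object$panel$area_ids,
    diff_trend_RR = exp(colMeans(d$delta)),
    diff_trend_lower = exp(apply(d$delta, 2, stats::quantile, 0.025)),
    diff_trend_upper = exp(apply(d$delta, 2, stats::quantile, 0.975)),
    residual_RR = exp(colMeans(resid_draws)),
    residual_lower = exp(apply(resid_draws, 2, stats::quantile, 0.025)),
    residual_upper = exp(apply(resid_draws, 2, stats::quantile, 0.975)),
    row.names = NULL)

  curves <- list()
  for (nm in names(d$f)) {
    fd <- d$f[[nm]]
    bn <- object$binning[[nm]]
    idx <- as.vector(bn$index)
    curves[[nm]] <- data.frame(
      bin = seq_along(bn$midpoints),
      value = bn$midpoints,
      n_obs = tabulate(idx, nbins = length(bn$midpoints)),
      RR = exp(colMeans(fd)),
      lower = exp(apply(fd, 2, stats::quantile, 0.025)),
      upper = exp(apply(fd, 2, stats::quantile, 0.975)))
  }

  trend <- NULL
  if (object$spec$trend == "rw2_dynamic") {
    td <- d$phi + d$psi
    trend <- data.frame(period = object$panel$periods,
                        RR = exp(colMeans(td)),
                        lower = exp(apply(td, 2, stats::quantile, 0.025)),
                        upper = exp(apply(td, 2, stats::quantile, 0.975)))
  }

  structure(list(family = object$spec$family, fixed = fixed, areas = areas,
                 curves = curves, trend = trend, dic = object$dic,
                 acceptance = object$acceptance, rhat = object$rhat,
                 hyperpriors = object$priors),
            class = "summary.stpois")
}

#' @export
print.summary.stpois <- function(x, ...) {
  cat("Bayesian space-time Poisson model [", x$family, "]\n\n", sep = "")
  cat("Relative risks (posterior mean, 95% CI):\n")
  fx <- x$fixed
  fx[-1] <- lapply(fx[-1], round, 3)
  print(fx, row.names = FALSE)
  for (nm in names(x$curves)) {
    cat("  ", nm, ": non-linear effect over ", nrow(x$curves[[nm]]),
        " bins\n", sep = "")
  }
  print(x$dic)
  cat("Max split-chain Rhat (fixed effects):",
      round(max(x$rhat, na.rm = TRUE), 3), "\n")
  invisible(x)
}

#' @export
print.stpois <- function(x, ...) {
  cat("Fitted space-time Poisson model [", x$spec$family, "]: ",
      length(x$panel$area_ids), " areas x ", length(x$panel$periods),
      " periods, ", length(x$draws$alpha), " stored draws\n", sep = "")
  print(x$dic)
  invisible(x)
}

#' @export
coef.stpois <- function(object, ...) {
  d <- object$draws
  out <- c(alpha = mean(d$alpha))
  if (ncol(d$beta)) out <- c(out, colMeans(d$beta))
  if (object$spec$trend == "linear_differential") {
    out <- c(out, gamma = mean(d$gamma))
  }
  out
}

#' @export
fitted.stpois <- function(object, ...) {
  eta_bar <- linear_predictor(object$spec, mean_state(object), object$panel,
                              object$binning)
  object$E * exp(eta_bar)
}

#' @export
residuals.stpois <- function(object, type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  mu <- fitted(object)
  r <- object$panel$counts - mu
  if (type == "pearson") r <- r / sqrt(mu)
  r
}

#' Posterior predictive count panels
#'
#' Draws `nsim` replicate count matrices: for each, a stored posterior draw
#' is selected at random and counts are sampled from
#' `Poisson(E * exp(eta))` at that draw.
#'
#' @param object a fitted [stpois()] model.
#' @param nsim number of replicates.
#' @param seed optional seed.
#' @param ... unused.
#' @return list of count matrices.
#' @export
simulate.stpois <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  S <- length(object$draws$alpha)
  lapply(seq_len(nsim), function(b) {
    s <- sample.int(S, 1)
    eta <- linear_predictor(object$spec, draw_state(object, s), object$panel,
                            object$binning)
    y <- object$panel$counts
    y[] <- stats::rpois(length(y), object$E * exp(eta))
    y
  })
}

#' Plot fitted non-linear effects or the temporal trend
#'
#' For models with RW2 covariate effects, draws the posterior-mean `exp(f)`
#' curve with its pointwise 95% CI per covariate; otherwise the fitted
#' temporal trend (relative risk by period).
#'
#' @param x a fitted [stpois()] model.
#' @param ... passed to the base plot call.
#' @export
plot.stpois <- function(x, ...) {
  sm <- summary(x)
  if (length(sm$curves)) {
    old <- graphics::par(mfrow = c(1, length(sm$curves)))
    on.exit(graphics::par(old))
    for (nm in names(sm$curves)) {
      cv <- sm$curves[[nm]]
      keep <- cv$n_obs > 0
      graphics::plot(cv$value[keep], cv$RR[keep], type = "l",
                     xlab = nm, ylab = "Relative risk", ...)
      graphics::lines(cv$value[keep], cv$lower[keep], lty = 2)
      graphics::lines(cv$value[keep], cv$upper[keep], lty = 2)
      graphics::abline(h = 1, col = "grey")
    }
  } else if (!is.null(sm$trend)) {
    graphics::plot(sm$trend$period, sm$trend$RR, type = "b",
                   xlab = "period", ylab = "Relative risk", ...)
  } else {
    tt <- time_index(x$spec, x$panel)
    rr <- exp(mean(x$draws$gamma) * tt)
    graphics::plot(x$panel$periods, rr, type = "b", xlab = "period",
                   ylab = "Relative risk (grand trend)", ...)
  }
  invisible(x)
}

#' Hyperprior sensitivity analysis
#'
#' Refits the model under each hyperprior setting in `prior_grid` and
#' reports, per reported fixed effect, the maximum absolute shift in the
#' posterior mean log relative risk relative to the first setting.
#'
#' @param panel,weights,spec,mcmc as in [stpois()].
#' @param prior_grid list of at least two [hyperpriors()] objects.
#' @param include_residual as in [stpois()].
#' @return data frame: one row per effect, columns `max_abs_shift` plus the
#'   per-setting posterior mean log-RRs.
#' @export
sensitivity_rerun <- function(panel, weights, spec, prior_grid,
                              mcmc = mcmc_config(), include_residual = TRUE) {
  if (length(prior_grid) < 2) stop("need >= 2 prior settings")
  fits <- lapply(prior_grid, function(pr) {
    stpois(panel, weights, spec, priors = pr, mcmc = mcmc,
           include_residual = include_residual)
  })
  mats <- lapply(fits, coef)
  est <- do.call(cbind, mats)
  colnames(est) <- paste0("setting", seq_along(fits))
  shift <- apply(abs(est - est[, 1]), 1, max)
  data.frame(term = rownames(est), max_abs_shift = shift, est,
             row.names = NULL)
}
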