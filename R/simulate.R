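#' Unit-square lattice of areas
#'
#' Deterministic rows x cols grid of unit squares labelled `"r_c"`, with its
#' queen-contiguity weights: the standard synthetic geography for
#' disease-mapping simulation studies (interior cells have 8 neighbours,
#' edges 5, corners 3).
#'
#' @param rows,cols lattice dimensions (>= 1).
#' @return list with `polygons` (named list of closed coordinate rings) and
#'   `weights` (binary [spatial_weights()]).
#' @export
make_lattice <- function(rows, cols) {
  stopifnot(rows >= 1, cols >= 1)
  polys <- list()
  for (r in seq_len(rows)) {
    for (cc in seq_len(cols)) {
      x0 <- cc - 1; y0 <- r - 1
      polys[[paste0(r, "_", cc)]] <- cbind(
        c(x0, x0 + 1, x0 + 1, x0, x0),
        c(y0, y0, y0 + 1, y0 + 1, y0))
    }
  }
  list(polygons = polys, weights = queen_adjacency(polys))
}

#' Simulation scenario for synthetic areal panels
#'
#' Describes a synthetic study: a rows x cols lattice of districts observed
#' over `n_periods` yearly periods, log-normal populations, a set of
#' spatially structured covariates (time-varying ones evolving by a
#' stationary AR(1)), and the true latent parameters of the generating
#' space-time model. The defaults emulate a national district panel:
#' 20 x 20 = 400 areas over 5 years, baseline rate 12 events per 100,000
#' person-years, and covariate effects of the magnitude typical for
#' ecological suicide regressions (income in EUR 1,000 per person,
#' unemployment in %, population density in people per km2 entered
#' log-transformed, plus four temporally constant health-system covariates).
#'
#' @param rows,cols lattice dimensions.
#' @param n_periods number of yearly periods (>= 2).
#' @param first_period first calendar year label.
#' @param baseline_rate events per person-year when all effects are zero.
#' @param pop_median,pop_sdlog log-normal population distribution per area.
#' @param covariates named list of covariate generator settings; each entry
#'   is a list with `mean`, `spatial_sd`, `noise_sd`, `static` (logical),
#'   `rho` (AR(1) persistence for time-varying covariates), `clip`
#'   (length-2 bounds), and optional `log_scale = TRUE` to generate the
#'   field on the log scale and store its exponential.
#' @param beta named vector of true log relative risks per covariate unit
#'   (log-scale units for `log_scale` covariates).
#' @param gamma true grand linear trend (log RR per period).
#' @param tau_u,tau_v,tau_delta true precisions of the scaled ICAR,
#'   unstructured and differential-slope fields.
#' @param tau_phi,tau_psi true precisions for the dynamic-trend variant.
#' @param nonlinear_truth optional list replacing one covariate's linear
#'   effect with a curve: `list(covariate =, type = "plateau"|"quadratic",
#'   ...)`. `"plateau"` rises linearly at `slope` per unit up to `peak`
#'   then stays flat (a pronounced effect that peaks and flattens out);
#'   `"quadratic"` is `-curvature * (x - center)^2`.
#' @return list of class `sim_scenario`.
#' @export
sim_scenario <- function(rows = 20, cols = 20, n_periods = 5,
                         first_period = 2007,
                         baseline_rate = 12 / 1e5,
                         pop_median = 2e5, pop_sdlog = 0.5,
                         covariates = default_covariate_generators(),
                         beta = default_true_beta(),
                         gamma = log(1.008),
                         tau_u = 100, tau_v = 400, tau_delta = 40000,
                         tau_phi = 1000, tau_psi = 10000,
                         nonlinear_truth = NULL) {
  stopifnot(rows >= 2 || cols >= 2, n_periods >= 2, baseline_rate > 0,
            tau_u > 0, tau_v > 0, tau_delta > 0)
  if (!all(names(beta) %in% names(covariates))) {
    stop("beta names must match covariate generators")
  }
  structure(list(rows = rows, cols = cols, n_periods = n_periods,
                 first_period = first_period, baseline_rate = baseline_rate,
                 pop_median = pop_median, pop_sdlog = pop_sdlog,
                 covariates = covariates, beta = beta, gamma = gamma,
                 tau_u = tau_u, tau_v = tau_v, tau_delta = tau_delta,
                 tau_phi = tau_phi, tau_psi = tau_psi,
                 nonlinear_truth = nonlinear_truth),
            class = "sim_scenario")
}

#' @rdname sim_scenario
#' @export
default_covariate_generators <- function() {
  list(
    income = list(mean = 28, spatial_sd = 1.5, noise_sd = 0.8, static = FALSE,
                  rho = 0.9, clip = c(15, 45)),
    unemployment = list(mean = 7, spatial_sd = 2.5, noise_sd = 1.2,
                        static = FALSE, rho = 0.9, clip = c(0.5, 20)),
    density = list(mean = 5.3, spatial_sd = 0.8, noise_sd = 0.4,
                   static = FALSE, rho = 0.95, clip = c(2.5, 9),
                   log_scale = TRUE),
    depression = list(mean = 8, spatial_sd = 1.2, noise_sd = 0.8,
                      static = TRUE, clip = c(3, 15)),
    gp = list(mean = 66, spatial_sd = 6, noise_sd = 5, static = TRUE,
              clip = c(40, 100)),
    psychiatrists = list(mean = 13, spatial_sd = 3, noise_sd = 2,
                         static = TRUE, clip = c(1, 30)),
    psychotherapists = list(mean = 20, spatial_sd = 5, noise_sd = 4,
                            static = TRUE, clip = c(1, 45)))
}

#' @rdname sim_scenario
#' @export
default_true_beta <- function() {
  c(income = log(0.994), unemployment = log(1.015), density = log(0.959),
    depression = 0, gp = log(1.003), psychiatrists = 0, psychotherapists = 0)
}

# one spatially structured field: scaled-ICAR draw * spatial_sd + iid noise
spatial_field <- function(icar_scaled, spatial_sd, noise_sd) {
  n <- icar_scaled$m
  s <- if (spatial_sd > 0) spatial_sd * sample_constrained(icar_scaled, 1)
       else numeric(n)
  s + stats::rnorm(n, 0, noise_sd)
}

#' Simulate covariate fields for a scenario
#'
#' Each covariate is its global mean plus a spatially structured component
#' (a scaled-ICAR draw) plus iid noise; time-varying covariates evolve as a
#' stationary AR(1) whose innovations are themselves spatially structured,
#' so spatial pattern persists over time. Values are clipped to the declared
#' plausibility bounds; `log_scale` covariates are exponentiated before
#' storage. A covariate with zero variances is constant at its mean; AR(1)
#' persistence 1 reproduces the temporally constant (static) case.
#'
#' @param scenario a [sim_scenario()].
#' @param weights a binary [spatial_weights()] for the scenario lattice.
#' @param seed optional integer seed.
#' @return named list of covariate values: vectors for static covariates,
#'   (areas x periods) matrices for time-varying ones.
#' @export
simulate_covariates <- function(scenario, weights, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  icar <- scale_structure(icar_structure(weights))
  n <- weights$n
  np <- scenario$n_periods
  out <- list()
  for (nm in names(scenario$covariates)) {
    g <- scenario$covariates[[nm]]
    rho <- if (isTRUE(g$static)) 1 else g$rho
    base <- g$mean + spatial_field(icar, g$spatial_sd, g$noise_sd)
    if (isTRUE(g$static)) {
      x <- pmin(pmax(base, g$clip[1]), g$clip[2])
      if (isTRUE(g$log_scale)) x <- exp(x)
      out[[nm]] <- x
    } else {
      dev <- base - g$mean
      m <- matrix(0, n, np)
      m[, 1] <- base
      if (np > 1) {
        innov_sd <- sqrt(max(0, 1 - rho^2))
        for (t in 2:np) {
          dev <- rho * dev +
            innov_sd * spatial_field(icar, g$spatial_sd, g$noise_sd)
          m[, t] <- g$mean + dev
        }
      }
      m <- pmin(pmax(m, g$clip[1]), g$clip[2])
      if (isTRUE(g$log_scale)) m <- exp(m)
      out[[nm]] <- m
    }
  }
  out
}

# true non-linear effect curve, centred to mean zero over the cells
nonlinear_curve <- function(nl, x) {
  fx <- switch(nl$type,
    plateau = nl$slope * pmin(x, nl$peak),
    quadratic = -nl$curvature * (x - nl$center)^2,
    stop("unknown nonlinear truth type: ", nl$type))
  fx - mean(fx)
}

#' Simulate a complete synthetic areal count panel
#'
#' Draws the latent fields of the generating model declared by `spec` from
#' their scaled GMRF structures (ICAR `u`, iid `v`, plus either differential
#' slopes `delta` around the grand trend `gamma`, or a dynamic RW2 + iid
#' trend), assembles the true log relative risk surface, and samples counts
#' `y_it ~ Poisson(E_it * exp(eta_it))` with `E_it = P_it * baseline_rate`.
#' The ground truth (all latent components, the true `eta`, and any true
#' non-linear curve evaluated per cell) is attached as `attr(panel,
#' "truth")`; the lattice weights and polygons as `attr(panel, "weights")` /
#' `attr(panel, "polygons")`.
#'
#' @param scenario a [sim_scenario()].
#' @param spec a [model_spec()] naming the generating family (its covariate
#'   roles decide nothing here; the trend type decides which temporal fields
#'   are drawn).
#' @param seed optional integer seed; the panel is a pure function of
#'   (scenario, spec, seed).
#' @return an [areal_panel()] with truth attributes.
#' @export
simulate_counts <- function(scenario, spec = model_spec("model1a",
                              covariates = names(scenario$covariates),
                              transforms = c(density = "log")),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lat <- make_lattice(scenario$rows, scenario$cols)
  w <- lat$weights
  n <- w$n
  np <- scenario$n_periods
  periods <- scenario$first_period + seq_len(np) - 1L

  covs <- simulate_covariates(scenario, w)
  pop <- scenario$pop_median * exp(stats::rnorm(n, 0, scenario$pop_sdlog))
  P <- matrix(pop, n, np)

  icar <- scale_structure(icar_structure(w))
  u <- sample_constrained(icar, scenario$tau_u)
  v <- stats::rnorm(n, 0, 1 / sqrt(scenario$tau_v))

  tt <- periods - periods[(np + 1L) %/% 2L]
  truth <- list(u = u, v = v, beta = scenario$beta, seed = seed,
                baseline_rate = scenario$baseline_rate)
  eta <- matrix(u + v, n, np)

  nl <- scenario$nonlinear_truth
  alpha0 <- 0
  for (nm in names(scenario$beta)) {
    g <- scenario$covariates[[nm]]
    x <- covs[[nm]]
    if (isTRUE(g$log_scale)) x <- log(x)
    xm <- if (is.matrix(x)) x else matrix(x, n, np)
    if (!is.null(nl) && identical(nl$covariate, nm)) {
      cm <- matrix(nonlinear_curve(nl, as.vector(xm)), n, np)
      truth$curve <- cm
      eta <- eta + cm
    } else {
      b <- scenario$beta[[nm]]
      # centre each covariate so the intercept stays near zero and rates
      # remain plausible; the offset is folded into the true intercept
      alpha0 <- alpha0 - b * mean(xm)
      eta <- eta + b * (xm - mean(xm))
    }
  }
  truth$alpha <- alpha0

  if (spec$trend == "linear_differential") {
    delta <- stats::rnorm(n, 0, 1 / sqrt(scenario$tau_delta))
    delta <- delta - mean(delta)
    truth$gamma <- scenario$gamma
    truth$delta <- delta
    eta <- eta + outer(scenario$gamma + delta, tt)
  } else {
    if (np < 3) stop("dynamic trend needs at least 3 periods")
    phi <- sample_constrained(scale_structure(rw2_structure(np)),
                              scenario$tau_phi)
    psi <- stats::rnorm(np, 0, 1 / sqrt(scenario$tau_psi))
    psi <- psi - mean(psi)
    truth$phi <- phi
    truth$psi <- psi
    eta <- eta + matrix(phi + psi, n, np, byrow = TRUE)
  }

  E <- P * scenario$baseline_rate
  mu <- E * exp(eta)
  if (any(mu > 1e9)) {
    stop("simulated Poisson mean exceeds 1e9; use smaller effect sizes")
  }
  y <- matrix(stats::rpois(n * np, mu), n, np)
  truth$eta <- eta

  panel <- areal_panel(w$ids, periods, y, P, covs,
                       units = c(income = "EUR 1,000", unemployment = "%",
                                 density = "people/km2", depression = "%",
                                 gp = "per 100,000",
                                 psychiatrists = "per 100,000",
                                 psychotherapists = "per 100,000"))
  attr(panel, "truth") <- truth
  attr(panel, "weights") <- w
  attr(panel, "polygons") <- lat$polygons
  panel
}
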