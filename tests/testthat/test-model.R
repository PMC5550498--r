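test_that("expected counts standardise internally and conserve the total", {
  p <- areal_panel(c("a", "b"), 2007, matrix(c(10L, 30L), 2),
                   matrix(c(1e5, 3e5), 2))
  E <- expected_counts(p)
  expect_equal(as.vector(E), c(10, 30))
  expect_equal(sum(E), sum(p$counts))

  p2 <- tiny_panel(5, 4, seed = 8)
  expect_equal(sum(expected_counts(p2)), sum(p2$counts), tolerance = 1e-10)

  # doubling the population halves the rate but leaves E unchanged
  p3 <- areal_panel(c("a", "b"), 2007, p$counts, 2 * p$population)
  expect_equal(expected_counts(p3), expected_counts(p), ignore_attr = TRUE)

  p0 <- areal_panel("a", 2007, matrix(0L), matrix(1e5))
  expect_error(expected_counts(p0), "all counts zero")
})

test_that("linear predictor assembles intercept, covariates and trend", {
  p <- tiny_panel(3, 5)
  spec <- model_spec("model1a", covariates = c("x1", "x2"))

  expect_equal(linear_predictor(spec, list(), p),
               matrix(0, 3, 5), ignore_attr = TRUE)

  # slope only, centred at the middle period (2009)
  st <- list(gamma = 0.008)
  eta <- linear_predictor(spec, st, p)
  expect_equal(eta[1, "2011"], 0.016, ignore_attr = TRUE)
  expect_equal(eta[1, "2007"], -0.016, ignore_attr = TRUE)
  expect_equal(eta[1, "2009"], 0, ignore_attr = TRUE)

  # single linear covariate with unit value doubles the risk at beta = log 2
  p1 <- areal_panel("a", 2007, matrix(4L), matrix(1e5),
                    covariates = list(x = matrix(1)))
  sp1 <- model_spec("model1a", covariates = "x")
  eta1 <- linear_predictor(sp1, list(beta = list(x = log(2))), p1)
  expect_equal(exp(eta1[1, 1]), 2)

  # log transform declared for a covariate is applied
  pd <- areal_panel("a", 2007, matrix(4L), matrix(1e5),
                    covariates = list(dens = matrix(exp(2))))
  spd <- model_spec("model1a", covariates = "dens",
                    transforms = c(dens = "log"))
  expect_equal(linear_predictor(spd, list(beta = list(dens = 0.5)), pd)[1, 1],
               1, ignore_attr = TRUE)
})

test_that("linear predictor is linear in the state components", {
  p <- tiny_panel(4, 3, seed = 2)
  spec <- model_spec("model1a", covariates = c("x1", "x2"))
  set.seed(5)
  mk_state <- function() {
    list(alpha = rnorm(1), beta = list(x1 = rnorm(1), x2 = rnorm(1)),
         gamma = rnorm(1), delta = rnorm(4) - mean(rnorm(4)),
         u = rnorm(4), v = rnorm(4))
  }
  s1 <- mk_state(); s2 <- mk_state()
  lincomb <- Map(function(a, b) {
    if (is.list(a)) Map(function(x, y) 2 * x + 3 * y, a, b)
    else 2 * a + 3 * b
  }, s1, s2)
  expect_equal(linear_predictor(spec, lincomb, p),
               2 * linear_predictor(spec, s1, p) +
                 3 * linear_predictor(spec, s2, p),
               tolerance = 1e-12)
})

test_that("dynamic trend enters as phi + psi per period", {
  p <- tiny_panel(2, 4)
  spec <- model_spec("null_dynamic")
  st <- list(phi = c(-0.3, -0.1, 0.1, 0.3), psi = c(0.05, -0.05, 0, 0))
  eta <- linear_predictor(spec, st, p)
  expect_equal(eta[1, ], st$phi + st$psi, ignore_attr = TRUE)
  expect_equal(eta[2, ], eta[1, ])
})

test_that("RW2 effects are piecewise constant through their bins", {
  n <- 30
  set.seed(7)
  p <- areal_panel(paste0("a", 1:n), 2007, matrix(rpois(n, 10), n),
                   matrix(1e5, n), covariates = list(x = matrix(runif(n), n)))
  spec <- model_spec("model1b", covariates = "x", nonlinear = "x", bins = 5)
  bn <- bin_covariate(p$covariates$x, 5)
  f <- c(-1, 2, 0, 1, -2)
  eta <- linear_predictor(spec, list(f = list(x = f)), p)
  expect_equal(as.vector(eta), f[as.vector(bn$index)])
  # nudging x within its bin leaves eta unchanged
  eps <- 0.4 * diff(bn$midpoints[1:2])
  p2 <- p
  p2$covariates$x <- matrix(bn$midpoints[bn$index] + eps, n)
  expect_equal(linear_predictor(spec, list(f = list(x = f)), p2,
                                binning = list(x = bn)), eta)
})

test_that("bin_covariate clamps out-of-range values with a warning", {
  b <- bin_covariate(c(0.1, 0.5, 0.9), m = 4, range = c(0, 1))
  expect_equal(as.vector(b$index), c(1L, 3L, 4L))
  expect_warning(b2 <- bin_covariate(c(-5, 0.5, 7), m = 4, range = c(0, 1)),
                 "clamped")
  expect_equal(as.vector(b2$index), c(1L, 3L, 4L))
})

test_that("Poisson log-likelihood: values, additivity, concavity", {
  one <- function(y, eta) poisson_loglik(matrix(y), matrix(1), matrix(eta))
  expect_equal(one(0, 0), -1)
  expect_equal(one(1, 0), -1)

  p <- tiny_panel(4, 3, seed = 3)
  E <- expected_counts(p)
  eta <- matrix(rnorm(12, 0, 0.2), 4, 3)
  whole <- poisson_loglik(p$counts, E, eta)
  parts <- poisson_loglik(p$counts[, 1, drop = FALSE],
                          E[, 1, drop = FALSE], eta[, 1, drop = FALSE]) +
    poisson_loglik(p$counts[, -1], E[, -1], eta[, -1])
  expect_equal(whole, parts, tolerance = 1e-10)

  # strict concavity in eta: negative second differences
  h <- 1e-3
  for (e0 in c(-1, 0, 1.5)) {
    d2 <- one(5, e0 + h) - 2 * one(5, e0) + one(5, e0 - h)
    expect_lt(d2, 0)
  }

  expect_error(poisson_loglik(matrix(1), matrix(1), matrix(NaN)),
               "non-finite")
})
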