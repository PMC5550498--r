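test_that("MCMC matches the quadrature posterior on a single cell", {
  fit <- toy_fit(seed = 4)
  expa <- exp(fit$draws$alpha)
  oracle <- quadrature_posterior(5, 1)
  se_mean <- batch_se(expa)
  expect_lt(abs(mean(expa) - oracle$mean), 3 * se_mean)
  se_sd <- batch_se((expa - mean(expa))^2) / (2 * sd(expa))
  expect_lt(abs(sd(expa) - oracle$sd), 3 * se_sd + 0.02 * oracle$sd)
})

test_that("chains are bit-identical under the same seed and config", {
  scen <- small_scenario(4, 4)
  p <- simulate_counts(scen, full_spec(), seed = 2)
  w <- attr(p, "weights")
  mc <- mcmc_config(600, 200, 2, seed = 99)
  f1 <- stpois(p, w, full_spec(), mcmc = mc)
  f2 <- stpois(p, w, full_spec(), mcmc = mc)
  expect_identical(f1$draws, f2$draws)
})

test_that("stored draws satisfy the sum-to-zero constraints", {
  scen <- small_scenario(5, 5)
  p <- simulate_counts(scen, full_spec(), seed = 3)
  w <- attr(p, "weights")
  fit <- stpois(p, w, full_spec(), mcmc = mcmc_config(800, 300, 5, seed = 1))
  expect_lt(max(abs(rowSums(fit$draws$u))), 1e-8)
  expect_lt(max(abs(rowSums(fit$draws$delta))), 1e-8)

  fitb <- stpois(p, w,
                 model_spec("model1b",
                            covariates = names(scen$covariates),
                            nonlinear = "unemployment", bins = 20,
                            transforms = c(density = "log")),
                 mcmc = mcmc_config(600, 200, 5, seed = 1))
  expect_lt(max(abs(rowSums(fitb$draws$f$unemployment))), 1e-8)

  fit2 <- stpois(p, w,
                 model_spec("model2", covariates = names(scen$covariates),
                            transforms = c(density = "log")),
                 mcmc = mcmc_config(600, 200, 5, seed = 1))
  expect_lt(max(abs(rowSums(fit2$draws$phi))), 1e-8)
  expect_lt(max(abs(rowSums(fit2$draws$psi))), 1e-8)
})

test_that("DIC reduces to the plug-in deviance for a degenerate posterior", {
  p <- areal_panel(c("a", "b"), 2007:2008,
                   matrix(c(4L, 6L, 5L, 7L), 2), matrix(1e5, 2, 2))
  spec <- model_spec("null_parametric")
  st <- list(alpha = 0.3, delta = c(0, 0), u = c(0.1, -0.1), v = c(0, 0),
             gamma = 0)
  res <- dic(list(st, st, st), panel = p, spec = spec)
  expect_equal(res$pD, 0, tolerance = 1e-9)
  expect_equal(res$DIC, res$Dbar, tolerance = 1e-9)
})

test_that("DIC on hand-written draws matches the direct formula", {
  p <- areal_panel("a", 2007, matrix(5L), matrix(1e5))
  spec <- model_spec("null_parametric")
  alphas <- c(-0.2, 0.1, 0.4)
  draws <- lapply(alphas, function(a) list(alpha = a))
  got <- dic(draws, panel = p, spec = spec)
  E <- expected_counts(p)[1, 1]
  dev <- function(a) -2 * dpois(5, E * exp(a), log = TRUE)
  Dbar <- mean(sapply(alphas, dev))
  Dhat <- dev(mean(alphas))
  expect_equal(got$Dbar, Dbar, tolerance = 1e-10)
  expect_equal(got$Dhat, Dhat, tolerance = 1e-10)
  expect_equal(got$DIC, Dbar + (Dbar - Dhat), tolerance = 1e-10)
  expect_error(dic(draws[1], panel = p, spec = spec), "at least 2")
})

test_that("DIC from a fit equals the stored-deviance computation", {
  scen <- small_scenario(4, 4)
  p <- simulate_counts(scen, full_spec(), seed = 7)
  w <- attr(p, "weights")
  fit <- stpois(p, w, full_spec(), mcmc = mcmc_config(400, 100, 10, seed = 2))
  # recompute Dbar from the stored component draws via the list method
  states <- lapply(seq_along(fit$draws$alpha), function(s) draw <- local({
    d <- fit$draws
    list(alpha = d$alpha[s], beta = as.list(d$beta[s, ]), gamma = d$gamma[s],
         delta = d$delta[s, ], u = d$u[s, ], v = d$v[s, ])
  }))
  ref <- dic(states, panel = p, spec = full_spec())
  expect_equal(fit$dic$Dbar, ref$Dbar, tolerance = 1e-8)
  expect_equal(fit$dic$DIC, ref$DIC, tolerance = 1e-8)
})

test_that("summaries expose RRs with ordered credibility intervals", {
  scen <- small_scenario(5, 5)
  p <- simulate_counts(scen, full_spec(), seed = 11)
  w <- attr(p, "weights")
  fit <- stpois(p, w, full_spec(), mcmc = mcmc_config(600, 200, 5, seed = 3))
  sm <- summary(fit)
  expect_true(all(sm$fixed$lower <= sm$fixed$upper))
  expect_true(all(sm$areas$residual_lower <= sm$areas$residual_upper))
  expect_setequal(sm$areas$area, p$area_ids)
  expect_equal(nrow(sm$fixed), 1 + 7 + 1)  # intercept, covariates, Year

  cf <- coef(fit)
  expect_named(cf, c("alpha", names(scen$covariates), "gamma"),
               ignore.order = TRUE)
  mu <- fitted(fit)
  expect_equal(dim(mu), dim(p$counts))
  expect_true(all(mu > 0))
  r <- residuals(fit)
  expect_equal(r, (p$counts - mu) / sqrt(mu), ignore_attr = TRUE)
  yr <- simulate(fit, nsim = 2, seed = 1)
  expect_length(yr, 2)
  expect_equal(dim(yr[[1]]), dim(p$counts))
})

test_that("iid-only sampler marginals are stable across seeds (KS check)", {
  scen <- small_scenario(3, 3)
  p <- simulate_counts(scen, model_spec("null_parametric"), seed = 13)
  w <- attr(p, "weights")
  spec <- model_spec("null_parametric")
  f1 <- stpois(p, w, spec, mcmc = mcmc_config(102000, 2000, 10, seed = 1),
               include_residual = FALSE)
  f2 <- stpois(p, w, spec, mcmc = mcmc_config(102000, 2000, 10, seed = 2),
               include_residual = FALSE)
  ks <- suppressWarnings(ks.test(f1$draws$alpha, f2$draws$alpha)$statistic)
  expect_lt(ks, 0.05)
})

test_that("sensitivity reruns quantify hyperprior robustness", {
  scen <- small_scenario(4, 4)
  p <- simulate_counts(scen, full_spec(), seed = 17)
  w <- attr(p, "weights")
  mc <- mcmc_config(500, 200, 5, seed = 6)

  expect_error(sensitivity_rerun(p, w, full_spec(), list(hyperpriors()), mc),
               ">= 2")

  same <- sensitivity_rerun(p, w, full_spec(),
                            list(hyperpriors(), hyperpriors()), mc)
  expect_equal(same$max_abs_shift, rep(0, nrow(same)))
})

test_that("divergent settings and mismatched inputs fail loudly", {
  scen <- small_scenario(3, 3)
  p <- simulate_counts(scen, full_spec(), seed = 1)
  w <- attr(p, "weights")
  expect_error(stpois(p, path_weights(4), full_spec()), "disagree")
  expect_error(stpois(p, w, model_spec("model1a", covariates = "nope")),
               "not in panel")
  expect_error(mcmc_config(100, 200), "n_iter")
})
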