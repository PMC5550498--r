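test_that("event rates are per-capita counts on the requested scale", {
  p <- areal_panel("a", 2007:2008, matrix(c(126, 0), 1),
                   matrix(c(1e6, 1e6), 1))
  expect_equal(event_rate(p)[1, ], c(`2007` = 12.6, `2008` = 0))
  expect_equal(event_rate(p, per = 1)[1, 1], 126 / 1e6,
               ignore_attr = TRUE)
  expect_equal(event_rate(p, period = 2007), c(a = 12.6))
})

test_that("Moran's I matches the brute-force double sum on random graphs", {
  set.seed(99)
  for (rep in 1:50) {
    n <- sample(5:200, 1)
    w <- row_standardize(random_weights(n, p = runif(1, 0.05, 0.3),
                                        seed = rep))
    x <- rnorm(n)
    expect_equal(morans_i(x, w), brute_moran(x, w), tolerance = 1e-12)
    y <- rnorm(n)
    expect_equal(bivariate_morans_i(x, y, w), brute_bivariate_moran(x, y, w),
                 tolerance = 1e-12)
  }
})

test_that("closed forms: complete graph and the symmetric path case", {
  # complete graph: I = -1/(n-1) for any non-constant values
  w4 <- row_standardize(complete_weights(4))
  expect_equal(morans_i(c(3, 1, 4, 1), w4), -1 / 3, tolerance = 1e-12)
  expect_equal(morans_i(rnorm(4), w4), -1 / 3, tolerance = 1e-12)

  # path a-b-c-d with values (1,1,-1,-1)
  wp <- row_standardize(path_weights(4))
  x <- c(1, 1, -1, -1)
  expect_equal(morans_i(x, wp), 0.5, tolerance = 1e-12)
  expect_equal(morans_i(x, wp), brute_moran(x, wp), tolerance = 1e-12)

  expect_error(morans_i(rep(2, 4), wp), "zero variance")
})

test_that("Moran's I agrees with an independent implementation", {
  skip_if_not_installed("ape")
  set.seed(3)
  w <- row_standardize(random_weights(40, p = 0.2, seed = 11))
  x <- rnorm(40)
  ref <- ape::Moran.I(x, dense_W(w), scaled = FALSE)
  expect_equal(morans_i(x, w), ref$observed, tolerance = 1e-10)
})

test_that("bivariate statistic reduces to univariate and has the K_n form", {
  w <- row_standardize(random_weights(30, seed = 5))
  x <- rnorm(30)
  expect_equal(bivariate_morans_i(x, x, w), morans_i(x, w),
               tolerance = 1e-12)

  # complete graph: I = -r/(n-1), r the Pearson correlation
  n <- 6
  wk <- row_standardize(complete_weights(n))
  x <- rnorm(n); y <- 0.5 * x + rnorm(n)
  expect_equal(bivariate_morans_i(x, y, wk), -cor(x, y) / (n - 1),
               tolerance = 1e-12)

  expect_error(bivariate_morans_i(x, rep(1, n), wk), "zero variance")
})

test_that("permutation pseudo-p hits the 1e-4 floor and is reproducible", {
  # strong cluster pattern on a lattice: observed I beats all permutations
  lat <- make_lattice(6, 6)
  w <- row_standardize(lat$weights)
  xy <- do.call(rbind, lapply(lat$polygons, colMeans))
  x <- xy[, 1] + 0.01 * rnorm(36)  # smooth gradient
  mt <- moran_test(x, w, n_perm = 9999, seed = 42)
  expect_equal(mt$pseudo_p, 1e-4)
  expect_true(all(mt$permuted < mt$statistic))

  mt2 <- moran_test(x, w, n_perm = 9999, seed = 42)
  expect_identical(mt2$pseudo_p, mt$pseudo_p)
  expect_identical(mt2$statistic, mt$statistic)

  # n_perm = 1 and a permuted value at least as extreme -> p = 1
  set.seed(1)
  x2 <- rnorm(36)
  mts <- replicate(20, {
    s <- sample.int(1e6, 1)
    moran_test(sample(x2), w, n_perm = 1, seed = s)$pseudo_p
  })
  expect_true(all(mts %in% c(0.5, 1)))
})

test_that("permutation distribution has mean -1/(n-1) and calibrated size", {
  n <- 30
  w <- row_standardize(random_weights(n, p = 0.2, seed = 8))
  set.seed(21)
  x <- rnorm(n)
  mt <- moran_test(x, w, n_perm = 2000, seed = 5)
  se <- sd(mt$permuted) / sqrt(length(mt$permuted))
  expect_lt(abs(mean(mt$permuted) - (-1 / (n - 1))), 4 * se)

  # under the null the rejection rate at 0.05 stays near 0.05
  set.seed(77)
  rej <- replicate(200, {
    moran_test(rnorm(n), w, n_perm = 199,
               seed = sample.int(1e6, 1))$pseudo_p <= 0.05
  })
  se_hat <- sqrt(0.05 * 0.95 / 200)
  expect_lt(abs(mean(rej) - 0.05), 3 * se_hat + 1e-9)
})

test_that("Spearman screening uses tie-corrected average ranks", {
  x <- c(1, 2, 2, 4); y <- c(1, 3, 2, 4)
  rho <- spearman_matrix(list(a = x, b = y))
  oracle <- cor(c(1, 2.5, 2.5, 4), c(1, 3, 2, 4))
  expect_equal(rho["a", "b"], oracle, tolerance = 1e-12)
  expect_equal(rho["b", "a"], rho["a", "b"])
  expect_equal(diag(rho), c(a = 1, b = 1))

  z <- rnorm(10)
  m <- spearman_matrix(list(x = z, cube = z^3, neg = -z))
  expect_equal(m["x", "cube"], 1)
  expect_equal(m["x", "neg"], -1)

  expect_warning(rc <- spearman_matrix(list(x = z, const = rep(1, 10))),
                 "constant")
  expect_true(all(is.na(rc["const", setdiff(colnames(rc), "const")])))
})

test_that("explore_panel reports per-period and lagged Moran tables", {
  scen <- small_scenario(6, 6)
  p <- simulate_counts(scen, full_spec(), seed = 9)
  w <- attr(p, "weights")
  ex <- explore_panel(p, w, n_perm = 99, seed = 4)
  expect_equal(nrow(ex$univariate), 5)
  expect_equal(nrow(ex$bivariate), 4)
  expect_true(all(ex$univariate$pseudo_p >= 1 / 100))
  ex2 <- explore_panel(p, w, n_perm = 99, seed = 4)
  expect_identical(ex, ex2)
})
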