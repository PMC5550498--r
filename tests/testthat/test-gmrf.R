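test_that("ICAR structure is the graph Laplacian with component constraints", {
  w <- path_weights(2)
  s <- icar_structure(w)
  expect_equal(unname(s$Q), matrix(c(1, -1, -1, 1), 2))
  expect_equal(s$rank_deficiency, 1L)
  expect_equal(unname(s$constraints), matrix(1, 1, 2))

  # two disconnected edges: d = 2, one sum-to-zero row per component
  w2 <- edge_weights(4, list(c(1, 2), c(3, 4)))
  s2 <- icar_structure(w2)
  expect_equal(s2$rank_deficiency, 2L)
  expect_equal(nrow(s2$constraints), 2L)
  # Q annihilates the per-component constant vectors
  for (k in 1:2) {
    v <- as.numeric(w2$components == k)
    expect_equal(as.vector(s2$Q %*% v), rep(0, 4), tolerance = 1e-12)
  }
})

test_that("ICAR quadratic form equals the pairwise difference sum", {
  set.seed(4)
  for (rep in 1:10) {
    w <- random_weights(25, p = 0.2, seed = rep + 40)
    s <- icar_structure(w)
    x <- rnorm(25)
    pairwise <- 0
    for (i in seq_len(25)) {
      for (j in w$neighbors[[i]]) {
        if (j > i) pairwise <- pairwise + (x[i] - x[j])^2
      }
    }
    expect_equal(quad_form(s, x), pairwise, tolerance = 1e-10)
    expect_gte(quad_form(s, x), 0)
  }
})

test_that("RW2 structure: stencil, null space, quadratic form", {
  s3 <- rw2_structure(3)
  expect_equal(unname(s3$Q),
               matrix(c(1, -2, 1, -2, 4, -2, 1, -2, 1), 3))
  s5 <- rw2_structure(5)
  expect_equal(unname(s5$Q[3, ]), c(1, -4, 6, -4, 1))
  expect_equal(s5$rank_deficiency, 2L)

  for (m in c(3, 7, 20)) {
    s <- rw2_structure(m)
    expect_equal(as.vector(s$Q %*% rep(1, m)), rep(0, m), tolerance = 1e-10)
    expect_equal(as.vector(s$Q %*% seq_len(m)), rep(0, m), tolerance = 1e-9)
    x <- rnorm(m)
    expect_equal(quad_form(s, x), sum(diff(x, differences = 2)^2),
                 tolerance = 1e-10)
  }
  expect_error(rw2_structure(2), "at least 3")
})

test_that("scaling fixes the geometric mean marginal variance at 1", {
  # eigendecomposition oracle on the 4-cycle ICAR
  w <- edge_weights(4, list(c(1, 2), c(2, 3), c(3, 4), c(4, 1)))
  s <- scale_structure(icar_structure(w))
  e <- eigen(s$Q, symmetric = TRUE)
  pos <- e$values > 1e-10
  V <- e$vectors[, pos, drop = FALSE]
  mv <- rowSums(sweep(V^2, 2, e$values[pos], "/"))
  expect_equal(exp(mean(log(mv))), 1, tolerance = 1e-6)

  # idempotence
  s2 <- scale_structure(s)
  expect_equal(s2$Q, s$Q, tolerance = 1e-12)
  expect_equal(s2$scale_factor, s$scale_factor, tolerance = 1e-10)

  # iid structure unchanged
  si <- scale_structure(iid_structure(5))
  expect_equal(si$Q, diag(5))
  expect_equal(si$scale_factor, 1)

  # RW2 scaling also normalises its generalized-inverse variances
  sr <- scale_structure(rw2_structure(12))
  er <- eigen(sr$Q, symmetric = TRUE)
  posr <- er$values > 1e-8 * max(er$values)
  Vr <- er$vectors[, posr, drop = FALSE]
  mvr <- rowSums(sweep(Vr^2, 2, er$values[posr], "/"))
  expect_equal(exp(mean(log(mvr))), 1, tolerance = 1e-6)
})

test_that("constrained sampling honours constraints, seed and covariance", {
  w <- edge_weights(4, list(c(1, 2), c(2, 3), c(3, 4), c(4, 1)))
  s <- scale_structure(icar_structure(w))
  x <- sample_constrained(s, tau = 2, seed = 11)
  expect_equal(sum(x), 0, tolerance = 1e-10)
  expect_identical(sample_constrained(s, tau = 2, seed = 11), x)
  expect_error(sample_constrained(s, tau = -1), "positive")

  # empirical covariance vs the constrained generalized inverse / tau
  tau <- 2.5
  set.seed(123)
  draws <- t(replicate(10000, sample_constrained(s, tau)))
  emp <- cov(draws)
  e <- eigen(s$Q, symmetric = TRUE)
  pos <- e$values > 1e-10
  V <- e$vectors[, pos, drop = FALSE]
  Sig <- V %*% diag(1 / e$values[pos]) %*% t(V) / tau
  lead <- abs(Sig) >= 0.25 * max(abs(Sig))
  expect_lt(max(abs(emp[lead] - Sig[lead]) / abs(Sig[lead])), 0.05)

  # RW2 draws are orthogonal to constant and linear trends
  sr <- scale_structure(rw2_structure(10))
  xr <- sample_constrained(sr, 1, seed = 3)
  expect_equal(sum(xr), 0, tolerance = 1e-10)
})

test_that("semi-definiteness holds and the null space is exact", {
  set.seed(10)
  structs <- list(icar_structure(random_weights(15, seed = 2)),
                  rw2_structure(9), iid_structure(6))
  for (s in structs) {
    for (r in 1:20) {
      expect_gte(quad_form(s, rnorm(s$m)), -1e-10)
    }
  }
  s <- rw2_structure(9)
  expect_equal(quad_form(s, 2 + 3 * seq_len(9)), 0, tolerance = 1e-8)
})

test_that("precision updates follow the conjugate Gamma closed form", {
  # shape a + (m-d)/2, rate b + x'Qx/2, checked on arbitrary settings
  s <- iid_structure(3)
  # hand case: prior (1, 5e-5), m-d = 3, quadratic form 2
  x <- c(1, 1, 0)  # x'x = 2
  set.seed(1)
  draws <- update_precision(x, s, prior = c(1, 5e-5), n = 20000)
  shape <- 1 + 1.5; rate <- 5e-5 + 1
  expect_equal(mean(draws), shape / rate,
               tolerance = 4 / sqrt(20000) * (sqrt(shape) / rate) /
                 (shape / rate))

  set.seed(2)
  for (rep in 1:5) {
    a <- runif(1, 0.5, 3); b <- runif(1, 1e-5, 0.1)
    w <- random_weights(12, p = 0.3, seed = rep + 60)
    s <- icar_structure(w)
    f <- sample_constrained(scale_structure(s), 1)
    q <- quad_form(s, f)
    dr <- update_precision(f, s, prior = c(a, b), n = 10000)
    shape <- a + (s$m - s$rank_deficiency) / 2
    rate <- b + q / 2
    se_mean <- sqrt(shape) / rate / sqrt(10000)
    expect_lt(abs(mean(dr) - shape / rate), 3 * se_mean)
    expect_lt(abs(var(dr) - shape / rate^2) / (shape / rate^2), 0.15)
  }

  # zero field: posterior Gamma(a + (m-d)/2, b)
  set.seed(3)
  dz <- update_precision(rep(0, 12), s, prior = c(2, 0.5), n = 20000)
  shape0 <- 2 + (s$m - s$rank_deficiency) / 2
  expect_equal(mean(dz), shape0 / 0.5,
               tolerance = 4 * sqrt(shape0) / 0.5 / sqrt(20000) / (shape0 / 0.5))
})
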