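# quadrature oracle for the one-cell intercept-only posterior:
# p(alpha | y) ~ exp(y*alpha - E*exp(alpha) - 0.5*prec0*alpha^2)
quadrature_posterior <- function(y, E, prec0 = 0.001) {
  logpost <- function(a) y * a - E * exp(a) - 0.5 * prec0 * a^2
  mode <- optimize(logpost, c(-10, 10), maximum = TRUE)$maximum
  norm <- integrate(function(a) exp(logpost(a) - logpost(mode)),
                    -20, 20, rel.tol = 1e-12)$value
  mom <- function(k) {
    integrate(function(a) exp(k * a + logpost(a) - logpost(mode)),
              -20, 20, rel.tol = 1e-12)$value / norm
  }
  m1 <- mom(1); m2 <- mom(2)
  list(mean = m1, sd = sqrt(m2 - m1^2))
}

batch_se <- function(x, nb = 50) {
  bs <- colMeans(matrix(x[seq_len(nb * (length(x) %/% nb))],
                        nrow = length(x) %/% nb))
  sd(bs) / sqrt(nb)
}

toy_fit <- function(seed = 1, n_iter = 25000, burnin = 5000) {
  p <- areal_panel("a", 2009, matrix(5L), matrix(1e5))
  w <- spatial_weights("a", list(integer(0)))
  stpois(p, w, model_spec("null_parametric"),
         mcmc = mcmc_config(n_iter, burnin, thin = 1, seed = seed),
         include_residual = FALSE, offset = matrix(1))
}
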