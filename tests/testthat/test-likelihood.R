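# The dependent double-hurdle log-likelihood: hand-computable single
# observations, separability at rho = 0, normalization, the latent-space
# quadrature oracle, and invariances.

one_obs_design <- function(y) design_matrices(matrix(1), matrix(1), y)

test_that("single-observation contributions match hand arithmetic", {
  p <- dh_parameters(theta = 0, beta = 0, sigma = 1, rho = 0)
  # zero outcome, both indices 0: 1 - Phi(0)^2 = 3/4
  expect_equal(as.numeric(dh_loglik(p, one_obs_design(0))), log(0.75),
               tolerance = 1e-12)
  # certain participation, modal residual: log phi(0)
  p2 <- dh_parameters(theta = 40, beta = 2, sigma = 1, rho = 0)
  expect_equal(as.numeric(dh_loglik(p2, one_obs_design(2))),
               -0.5 * log(2 * pi), tolerance = 1e-12)
})

test_that("rho = 0 separates the likelihood into participation and amount parts", {
  for (variant in c("linear", "exponential")) {
    dm <- simple_dgp(400, rho = 0.4, seed = 31, variant = variant)  # data rho irrelevant
    p <- dh_parameters(theta = c(0.4, -0.6),
                       beta = if (variant == "linear") c(1.8, 0.9) else c(1.2, 0.4),
                       sigma = 1.4, rho = 0, variant = variant)
    parts <- dh_loglik_parts(p, dm)
    expect_equal(parts$total, as.numeric(dh_loglik(p, dm)), tolerance = 1e-10)
    if (variant == "exponential") {
      # participation part is a plain probit log-likelihood here
      d <- as.numeric(dm$y > 0)
      q <- drop(dm$z %*% p$theta)
      ll_probit <- sum(d * pnorm(q, log.p = TRUE) +
                         (1 - d) * pnorm(-q, log.p = TRUE))
      expect_equal(parts$participation, ll_probit, tolerance = 1e-10)
    }
  }
})

test_that("zero probability plus the integrated positive density is one", {
  for (rho in c(-0.7, 0, 0.7)) {
    for (case in list(list(v = "linear", q = 0.3, m = 1.5, s = 1.2),
                      list(v = "linear", q = -0.4, m = 0.8, s = 0.9),
                      list(v = "exponential", q = 0.5, m = 1.0, s = 0.8))) {
      p <- dh_parameters(theta = case$q, beta = case$m, sigma = case$s,
                         rho = rho, variant = case$v)
      total <- dh_zero_prob(p, case$q, case$m) +
        stats::integrate(function(y) dh_density(y, p, case$q, case$m),
                         0, Inf, rel.tol = 1e-10, abs.tol = 1e-12)$value
      expect_equal(total, 1, tolerance = 1e-6)
    }
  }
})

test_that("positive-outcome contributions match latent-space quadrature at rho = 0.5", {
  dm <- simple_dgp(200, rho = 0.5, seed = 13)
  p <- dh_parameters(theta = c(0.5, -0.8), beta = c(2, 1), sigma = 1.5, rho = 0.5)
  ll <- dh_loglik(p, dm, by_observation = TRUE)
  q <- drop(dm$z %*% p$theta)
  m <- drop(dm$X %*% p$beta)
  pos <- which(dm$y > 0)
  s2 <- p$sigma * sqrt(1 - p$rho^2)
  for (i in pos[1:25]) {
    # f(y) = int_{-q}^{inf} phi(eps) N(y; m + rho sigma eps, sigma^2(1-rho^2)) deps
    oracle <- stats::integrate(function(e)
      stats::dnorm(e) * stats::dnorm(dm$y[i], m[i] + p$rho * p$sigma * e, s2),
      -q[i], Inf, rel.tol = 1e-12, abs.tol = 1e-14)$value
    expect_equal(ll[i], log(oracle), tolerance = 1e-8)
  }
})

test_that("log-likelihood is invariant under row permutation", {
  dm <- simple_dgp(300, seed = 8)
  p <- dh_parameters(c(0.5, -0.8), c(2, 1), 1.5, 0.5)
  set.seed(99)
  perm <- sample(300)
  dmp <- design_matrices(dm$z[perm, ], dm$X[perm, ], dm$y[perm])
  expect_equal(as.numeric(dh_loglik(p, dm)), as.numeric(dh_loglik(p, dmp)),
               tolerance = 1e-10)
})

test_that("contract violations raise errors", {
  dm <- simple_dgp(50)
  expect_error(dh_loglik(dh_parameters(c(1, 2, 3), c(2, 1), 1.5), dm), "theta")
  expect_error(dh_loglik(dh_parameters(c(1, 2), c(2, 1, 0), 1.5), dm), "beta")
  expect_error(design_matrices(matrix(1, 2, 1), matrix(1, 2, 1), c(-1, 2)),
               "non-negative")
  expect_error(dh_parameters(0, 0, sigma = 0), "sigma")
})
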