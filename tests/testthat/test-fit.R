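# Estimation: starting fits, joint MLE recovery, nesting, inference
# helpers and model-implied predictions.

test_that("intercept-only probit with half ones estimates theta = 0", {
  z <- matrix(1, 200, 1, dimnames = list(NULL, "(Intercept)"))
  d <- rep(c(0, 1), 100)
  fit <- probit_fit(z, d)
  expect_equal(unname(fit$theta), 0, tolerance = 1e-8)
  expect_error(probit_fit(z, rep(1, 200)), "both")
})

test_that("perfect separation triggers a warning and finite estimates", {
  set.seed(4)
  x <- stats::rnorm(200)
  z <- cbind(1, x)
  d <- as.numeric(x > 0)
  expect_warning(fit <- probit_fit(z, d), "separation")
  expect_true(all(is.finite(fit$theta)))
})

test_that("truncated-normal regression recovers a known truncated sample", {
  set.seed(21)
  y <- stats::rnorm(60000, 1, 1)
  y <- y[y > 0][1:20000]
  X <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  fit <- trunc_reg_fit(X, y)
  expect_true(fit$converged)
  se <- sqrt(diag(fit$vcov))
  expect_lt(abs(fit$beta[[1]] - 1), 3 * se[1])
  expect_lt(abs(fit$sigma - 1), 3 * se[2])
  expect_error(trunc_reg_fit(X, c(-1, y[-1])), "positive")
})

test_that("joint MLE recovers the generating parameters within 3 SEs", {
  truth <- c(0.5, -0.8, 2, 1, 1.5, 0.5)
  fit <- fit_dh(simple_dgp(10000, seed = 1))
  expect_true(fit$converged)
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  expect_true(all(abs(est - truth) < 3 * se))
})

test_that("the free-rho fit never has lower likelihood than the fixed-zero fit", {
  dm <- simple_dgp(3000, seed = 5)
  free <- fit_dh(dm, rho_mode = "free")
  fixed <- fit_dh(dm, rho_mode = "fixed_zero")
  expect_gte(free$loglik, fixed$loglik - 1e-8)
  cmp <- lr_test(free, fixed)
  expect_equal(cmp$df, 1)
  expect_gte(cmp$chi2, 0)
})

test_that("rho is recovered near zero when errors are independent", {
  fit <- fit_dh(simple_dgp(5000, rho = 0, seed = 9), fit_null = FALSE)
  se_rho <- sqrt(vcov(fit)["rho", "rho"])
  expect_lt(abs(fit$params$rho), 3 * se_rho)
})

test_that("degenerate outcomes are rejected with guidance", {
  dm <- simple_dgp(100, seed = 2)
  all0 <- design_matrices(dm$z, dm$X, rep(0, 100))
  allp <- design_matrices(dm$z, dm$X, abs(dm$y) + 1)
  expect_error(fit_dh(all0), "probit")
  expect_error(fit_dh(allp), "truncated regression")
  rankdef <- design_matrices(cbind(dm$z, dup = dm$z[, 2]), dm$X, dm$y)
  expect_error(fit_dh(rankdef), "rank deficient")
})

test_that("the fitted point is a local maximum against 1-SE perturbations", {
  dm <- simple_dgp(2000, seed = 3)
  fit <- fit_dh(dm, fit_null = FALSE)
  se <- sqrt(diag(vcov(fit)))
  base <- fit$loglik
  est <- coef(fit)
  for (j in seq_along(est)) {
    for (dir in c(-1, 1)) {
      pert <- est
      pert[j] <- pert[j] + dir * se[j]
      rho_p <- if ("rho" %in% names(pert)) max(min(pert[["rho"]], 0.999), -0.999) else 0
      pp <- dh_parameters(pert[1:2], pert[3:4], max(pert[["sigma"]], 1e-6), rho_p)
      expect_lt(as.numeric(dh_loglik(pp, dm)), base + 1e-8)
    }
  }
})

test_that("Wald test arithmetic and edge cases", {
  fake <- structure(list(params = dh_parameters(0, 0, 1, rho = 0.2),
                         rho_mode = "free",
                         vcov = matrix(0.01, 1, 1,
                                       dimnames = list("rho", "rho"))),
                    class = "dh_fit")
  w <- wald_rho_test(fake)
  expect_equal(w$statistic, 4, tolerance = 1e-12)
  expect_equal(w$p_value, stats::pchisq(4, 1, lower.tail = FALSE))
  fake$params$rho <- 0
  w0 <- wald_rho_test(fake)
  expect_equal(w0$statistic, 0)
  expect_equal(w0$p_value, 1)
})

test_that("LR statistic and pseudo R-squared arithmetic", {
  fit <- fit_dh(simple_dgp(1500, seed = 12))
  expect_equal(fit$lr_chi2, 2 * (fit$loglik - fit$loglik_null), tolerance = 1e-10)
  expect_gte(fit$lr_chi2, 0)
  expect_equal(pseudo_r2(fit), 1 - fit$loglik / fit$loglik_null, tolerance = 1e-12)
  # pure arithmetic: ll = -5700 vs -5800
  fake <- structure(list(loglik = -5700, loglik_null = -5800), class = "dh_fit")
  expect_equal(pseudo_r2(fake), 1 - 5700 / 5800, tolerance = 1e-12)
  expect_equal(2 * (fake$loglik - fake$loglik_null), 200)
})

test_that("informative covariates yield larger LR statistics than noise", {
  strong <- fit_dh(simple_dgp(2000, theta = c(0.5, -1), beta = c(2, 1.5), seed = 6))
  noise <- fit_dh(simple_dgp(2000, theta = c(0.5, 0), beta = c(2, 0), seed = 6))
  expect_gt(strong$lr_chi2, noise$lr_chi2)
  expect_lt(stats::pchisq(strong$lr_chi2, strong$lr_df, lower.tail = FALSE), 0.05)
})

test_that("participation probability is Phi(z theta), monotone, and 1/2 at zero", {
  p <- dh_parameters(c(0, 1), c(1, 1), 1, rho = 0)
  expect_equal(predict_participation(p, c(1, 0)), 0.5)
  grid <- cbind(1, seq(-3, 3, 0.5))
  probs <- predict_participation(p, grid)
  expect_true(all(diff(probs) > 0))
  expect_true(all(probs >= 0 & probs <= 1))
})

test_that("expected spending: closed hurdle, closed form, and Monte-Carlo oracle", {
  p <- dh_parameters(c(0.5), c(2), 1.5, rho = 0)
  expect_lt(predict_expected_y(dh_parameters(-30, 2, 1.5), 1, 1), 1e-12)
  # rho = 0 closed form equals direct quadrature
  closed <- predict_expected_y(p, 1, 1)
  byquad <- stats::integrate(function(u) (2 + 1.5 * u) * stats::dnorm(u) *
                               stats::pnorm(0.5), -2 / 1.5, Inf)$value
  expect_equal(closed, byquad, tolerance = 1e-6)
  # rho = 0.5 matches a large Monte-Carlo sample
  p5 <- dh_parameters(0.5, 2, 1.5, rho = 0.5)
  set.seed(14)
  n <- 1e6
  eps <- stats::rnorm(n)
  v <- 1.5 * (0.5 * eps + sqrt(0.75) * stats::rnorm(n))
  ysim <- ifelse(0.5 + eps > 0 & 2 + v > 0, 2 + v, 0)
  mc_se <- stats::sd(ysim) / sqrt(n)
  expect_lt(abs(predict_expected_y(p5, 1, 1) - mean(ysim)), 3 * mc_se)
  # exponential variant, rho = 0: Phi(q) * lognormal mean
  pe <- dh_parameters(0.5, 1, 0.8, rho = 0, variant = "exponential")
  expect_equal(predict_expected_y(pe, 1, 1),
               pnorm(0.5) * exp(1 + 0.8^2 / 2), tolerance = 1e-10)
})
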