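# Synthetic household generator: determinism, degenerate configurations,
# agreement of the empirical zero share with the model's closed form, and
# conditional normality of log-amounts in the exponential variant.

test_that("identical configurations give bit-identical tables", {
  cfg <- synthetic_config(500, seed = 17)
  a <- simulate_households(cfg)
  b <- simulate_households(synthetic_config(500, seed = 17))
  expect_identical(a, b)
  d <- simulate_households(synthetic_config(500, seed = 18))
  expect_false(identical(a$oop_pharma, d$oop_pharma))
})

test_that("invalid configurations are rejected", {
  bad <- default_covariate_freqs()
  bad$head_gender <- c(female = 0.6, male = 0.5)
  expect_error(synthetic_config(100, covariate_freqs = bad), "sum to 1")
  bad$head_gender <- c(female = -0.1, male = 1.1)
  expect_error(synthetic_config(100, covariate_freqs = bad), "non-negative")
  expect_error(synthetic_config(0), "positive integer")
  expect_error(dh_parameters(0, 0, sigma = -1), "sigma")
  expect_error(dh_parameters(0, 0, sigma = 1, rho = 1), "rho")
})

test_that("a closed participation hurdle yields all zeros; an open one all positives", {
  closed <- synthetic_config(1000, seed = 1, outcome_variant = "linear",
                             true_params = full_params(-10, 5, 1),
                             zero_share_target = NULL)
  expect_true(all(simulate_households(closed)$oop_pharma == 0))
  open <- synthetic_config(1000, seed = 1, outcome_variant = "linear",
                           true_params = full_params(10, 5, 0.01),
                           zero_share_target = NULL)
  y <- simulate_households(open)$oop_pharma
  expect_true(all(y > 0))
  expect_lt(abs(mean(y) - 5), 0.01)
})

test_that("empirical zero share matches the closed-form model probability", {
  cfg <- synthetic_config(100000, seed = 11, outcome_variant = "linear")
  hh <- simulate_households(cfg)
  tp <- cfg$true_params
  dm <- encode_design(hh)
  p0 <- mean(dh_zero_prob(tp, drop(dm$z %*% tp$theta), drop(dm$X %*% tp$beta)))
  emp <- mean(hh$oop_pharma == 0)
  mc_se <- sqrt(p0 * (1 - p0) / nrow(hh))
  expect_lt(abs(emp - p0), 3 * mc_se)
  # calibration puts the population share at the survey's 2988/9381
  expect_lt(abs(emp - 2988 / 9381), 0.01)
})

test_that("exponential-variant log amounts are conditionally normal at rho = 0", {
  tp <- full_params(0.5, 5, 1.2, rho = 0, variant = "exponential")
  cfg <- synthetic_config(10000, seed = 23, outcome_variant = "exponential",
                          true_params = tp, zero_share_target = NULL)
  hh <- simulate_households(cfg)
  pos <- hh$oop_pharma > 0
  expect_true(all(hh$oop_pharma[pos] > 0))
  dm <- encode_design(hh)
  m <- drop(dm$X %*% tp$beta)
  r <- (log(hh$oop_pharma[pos]) - m[pos]) / tp$sigma
  expect_gt(suppressWarnings(stats::ks.test(r, "pnorm")$p.value), 0.01)
})

test_that("Rial emission scales the monetary columns by 129,000", {
  usd <- simulate_households(synthetic_config(200, seed = 3))
  irr <- simulate_households(synthetic_config(200, seed = 3, currency = "IRR"))
  expect_equal(irr$income, usd$income * 129000)
  expect_equal(irr$oop_pharma, usd$oop_pharma * 129000)
  expect_identical(irr$head_gender, usd$head_gender)
})

test_that("household CSV round-trips", {
  hh <- simulate_households(synthetic_config(50, seed = 9))
  path <- withr::local_tempfile(fileext = ".csv")
  write_households(hh, path)
  back <- read_households(path)
  expect_equal(back$oop_pharma, hh$oop_pharma, tolerance = 1e-12)
  expect_identical(back$education, hh$education)
  hh$income[2] <- NA
  expect_error(write_households(hh, path), "missing")
})
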