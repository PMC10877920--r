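# Descriptive stage: currency conversion, elderly filtering, grouped
# summaries, zero accounting and extremes.

test_that("Rial-to-USD conversion is exact, linear and guarded", {
  expect_equal(convert_rial_to_usd(129000), 1)
  expect_equal(convert_rial_to_usd(0), 0)
  expect_equal(convert_rial_to_usd(258000), 2)
  x <- c(1, 10, 129000, 5e9)
  expect_equal(convert_rial_to_usd(3 * x), 3 * convert_rial_to_usd(x))
  expect_true(all(diff(convert_rial_to_usd(sort(x))) > 0))
  expect_error(convert_rial_to_usd(-5), "non-negative")
})

test_that("elderly filtering keeps households with a member aged 65 or more", {
  tab <- data.frame(id = 1:4,
                    member_ages = c("40;70", "40;64", "65", "20;30;40"),
                    stringsAsFactors = FALSE)
  kept <- filter_elderly_households(tab)
  expect_identical(kept$id, c(1L, 3L))
  flag <- data.frame(id = 1:3, has_elderly = c(TRUE, FALSE, TRUE))
  expect_identical(filter_elderly_households(flag)$id, c(1L, 3L))
  expect_error(filter_elderly_households(data.frame(id = 1)), "member_ages")
})

test_that("group percents reproduce count/total arithmetic to 2 dp", {
  tab <- data.frame(
    head_gender = rep(c("female", "male"), c(2611, 6770)),
    oop_pharma = 0)
  gs <- group_summary(tab, "head_gender")
  expect_equal(round(gs$percent[gs$level == "female"], 2), 27.83)
  expect_equal(round(gs$percent[gs$level == "male"], 2), 72.17)
  expect_equal(sum(gs$frequency), 9381)
  expect_lt(abs(sum(round(gs$percent, 2)) - 100), 0.05)
})

test_that("group summaries partition the table and compute textbook moments", {
  hh <- simulate_households(synthetic_config(2000, seed = 31))
  for (v in c("education", "ownership", "family_size_group")) {
    gs <- group_summary(hh, v)
    expect_equal(sum(gs$frequency), nrow(hh))
    expect_lt(abs(sum(gs$percent) - 100), 1e-9)
    expect_true(all(gs$sd_oop >= 0, na.rm = TRUE))
  }
  toy <- data.frame(education = "primary", oop_pharma = c(1, 2, 3))
  gs <- group_summary(toy, "education")
  row <- gs[gs$level == "primary", ]
  expect_equal(row$frequency, 3)
  expect_equal(row$percent, 100)
  expect_equal(row$mean_oop, 2)
  expect_equal(row$sd_oop, 1)
})

test_that("zero-spending share is exact", {
  allpos <- data.frame(oop_pharma = c(1, 2, 3))
  expect_equal(zero_share(allpos), list(n_zero = 0L, n_total = 3L, share = 0))
  survey_like <- data.frame(oop_pharma = rep(c(0, 5), c(2988, 9381 - 2988)))
  zs <- zero_share(survey_like)
  expect_equal(zs$n_zero, 2988)
  expect_equal(zs$share, 2988 / 9381, tolerance = 1e-12)
  expect_equal(round(zs$share, 4), 0.3185)
  allzero <- data.frame(oop_pharma = numeric(4))
  expect_equal(zero_share(allzero)$share, 1)
})

test_that("extremes: minimum over positives, maximum, and mean conventions", {
  tab <- data.frame(oop_pharma = c(0, 5, 10))
  ex <- oop_extremes(tab)
  expect_equal(ex$min_positive, 5)
  expect_equal(ex$max, 10)
  expect_equal(ex$mean, 5)
  expect_equal(oop_extremes(tab, include_zeros_in_mean = FALSE)$mean, 7.5)
  one <- data.frame(oop_pharma = 7)
  expect_equal(oop_extremes(one)$min_positive, 7)
  expect_equal(oop_extremes(one)$max, 7)
  # independent recomputation on a synthetic table
  hh <- simulate_households(synthetic_config(500, seed = 77))
  ex2 <- oop_extremes(hh)
  y <- sort(hh$oop_pharma)
  expect_equal(ex2$min_positive, y[y > 0][1])
  expect_equal(ex2$max, y[length(y)])
  expect_equal(ex2$mean, sum(y) / length(y), tolerance = 1e-12)
})
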