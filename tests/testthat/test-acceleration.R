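test_that("log-log slope recovers a power-law exponent exactly", {
  for (m in c(0.5, 2, 4, 6.25)) {
    for (cs in c(1e-6, 1, 250)) {
      ages <- c(27.5, 32.5, 37.5, 62.5, 87.5)
      est <- loglog_slope(ages, cs * ages^m)
      expect_equal(est$slope, m, tolerance = 1e-12)
      expect_equal(est$intercept, log(cs), tolerance = 1e-9)
      expect_equal(est$n_points, 5L)
    }
  }
})

test_that("log-log slope matches lm and the grid-refinement oracle", {
  # published-cohort spot checks
  s1 <- loglog_slope(c(27.5, 32.5, 37.5), c(4.7, 7.4, 10.1))
  expect_equal(s1$slope, 2.47, tolerance = 0.005)
  s2 <- loglog_slope(c(82.5, 87.5), c(9.5, 17.0))
  expect_equal(s2$slope, log(17.0 / 9.5) / log(87.5 / 82.5),
               tolerance = 1e-12)  # two-point closed form
  # cross-checks on random instances
  set.seed(7)
  for (rep in 1:25) {
    n <- sample(2:8, 1)
    ages <- sort(sample(seq(27.5, 87.5, 5), n))
    rates <- exp(rnorm(n, 2, 1.5))
    mine <- loglog_slope(ages, rates)$slope
    via_lm <- unname(coef(lm(log(rates) ~ log(ages)))[2])
    expect_equal(mine, via_lm, tolerance = 1e-10)
    expect_equal(mine, grid_slope_oracle(ages, rates), tolerance = 1e-6)
  }
})

test_that("non-positive rates are excluded with a warning; <2 points gives NA slope", {
  expect_warning(est <- loglog_slope(c(27.5, 32.5, 37.5), c(0, 7.4, 10.1)),
                 "excluded")
  expect_equal(est$n_points, 2L)
  expect_equal(est$slope, log(10.1 / 7.4) / log(37.5 / 32.5))
  expect_warning(short <- loglog_slope(c(27.5, 32.5), c(0, 5)), "excluded")
  expect_true(is.na(short$slope))
  expect_true(is.na(loglog_slope(c(27.5, 32.5), c(NA, 5))$slope))
})

test_that("slopes are invariant to rate rescaling and to the log base", {
  ages <- c(27.5, 42.5, 62.5, 87.5)
  rates <- c(3.1, 8.2, 24.5, 60.1)
  base <- loglog_slope(ages, rates)$slope
  expect_equal(loglog_slope(ages, 1e4 * rates)$slope, base,
               tolerance = 1e-13)
  # base-10 OLS done independently
  x <- log10(ages); y <- log10(rates)
  b10 <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(base, b10, tolerance = 1e-13)
})

test_that("common_bands intersects the usable supports of two cohorts", {
  gb <- gb_melanoma_males()
  expect_equal(common_bands(gb, 1895, 1900)$label, c("80-84", "85+"))
  expect_equal(common_bands(gb, 1970, 1975)$label,
               c("25-29", "30-34", "35-39"))
  # disjoint supports
  expect_equal(nrow(common_bands(gb, 1895, 1975)), 0)
  expect_error(common_bands(gb, 1895, 1880), "not present")
})

test_that("pair_ratio reproduces published cells and honours restriction", {
  gb <- gb_melanoma_males()
  p75 <- pair_ratio(gb, 1975)
  expect_lt(abs(p75$log2_ratio - (-0.28)), 0.02)
  expect_equal(nrow(p75$common_bands), 3)
  p20 <- pair_ratio(gb, 1920)
  expect_lt(abs(p20$log2_ratio - (-0.04)), 0.02)
  expect_equal(nrow(p20$common_bands), 6)

  # identical rate vectors -> ratio exactly 0
  bands <- std_bands()[1:4, ]
  same <- cohort_table(c(1900, 1905), bands,
                       rbind(c(2, 4, 7, 11), c(2, 4, 7, 11)))
  expect_identical(pair_ratio(same, 1905)$log2_ratio, 0)

  # adding a band only one cohort observes must not change the ratio
  aug <- cohort_table(c(1900, 1905), bands,
                      rbind(c(2, 4, 7, NA), c(3, 5, 9, 20)))
  trimmed <- cohort_table(c(1900, 1905), bands[1:3, ],
                          rbind(c(2, 4, 7), c(3, 5, 9)))
  expect_equal(pair_ratio(aug, 1905)$log2_ratio,
               pair_ratio(trimmed, 1905)$log2_ratio, tolerance = 1e-13)

  # < 2 common bands or a non-positive slope yields a missing ratio
  sparse <- cohort_table(c(1900, 1905), bands,
                         rbind(c(2, NA, NA, NA), c(3, 5, NA, NA)))
  expect_true(is.na(pair_ratio(sparse, 1905)$log2_ratio))
  declining <- cohort_table(c(1900, 1905), bands,
                            rbind(c(2, 4, 7, 11), c(9, 7, 5, 3)))
  expect_true(is.na(pair_ratio(declining, 1905)$log2_ratio))
  expect_error(pair_ratio(gb, 1890), "absent")
})

test_that("summarize_ratios computes mean, n-1 SE and mean:SE", {
  s <- summarize_ratios(c(-1, 1))
  expect_equal(s$mean, 0)
  expect_equal(s$z, 0)
  r <- c(-0.1, -0.2, -0.4, 0.1)
  s2 <- summarize_ratios(r)
  expect_equal(s2$mean, mean(r))
  expect_equal(s2$se, sd(r) / 2)
  expect_equal(s2$z * s2$se, s2$mean)
  # mean of logs is the log of the geometric mean of the ratios
  expect_equal(s2$mean, log2(prod(2^r)^(1 / 4)))
  expect_error(summarize_ratios(c(-0.1, NA)), "fewer than 2")
  expect_error(summarize_ratios(rep(-0.1, 5)), "zero standard error")
})

test_that("pointwise acceleration is the log-log difference quotient at geometric-mean ages", {
  ages <- std_bands()$rep_age
  # exact power law -> constant curve at m
  cv <- pointwise_acceleration(std_bands(), 0.01 * ages^3.5)
  expect_equal(cv$acceleration, rep(3.5, 12), tolerance = 1e-12)
  expect_equal(cv$age, sqrt(ages[-13] * ages[-1]))
  # two-point cohort -> single closed-form point
  one <- pointwise_acceleration(c(82.5, 87.5), c(9.5, 17.0))
  expect_equal(nrow(one), 1)
  expect_equal(one$acceleration, log(17.0 / 9.5) / log(87.5 / 82.5))
  expect_equal(one$age, sqrt(82.5 * 87.5))
  # monotone rates -> positive curve
  up <- pointwise_acceleration(ages, cumsum(runif(13, 1, 3)))
  expect_true(all(up$acceleration > 0))
  expect_error(pointwise_acceleration(c(27.5, 32.5), c(0, 5)), "at least 2")
})
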